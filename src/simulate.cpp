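// Euler-Maruyama Monte Carlo integrators: the full conductance-based LIF
// network, the reduced effective single cell, and a Poisson-driven
// second-order alpha synapse (for conductance-moment checks).

#include <Rcpp.h>
#include <random>
#include <vector>

using namespace Rcpp;

// Full network. Voltage (below threshold):
//   tau_m dv_i = [ -v_i - gE_i (v_i - EE) - gI_i (v_i - EI) ] dt
//                + sigma_i sqrt(tau_m) dW_i
// Synapses per incoming channel X:
//   tau_d_X g'   = -g + g1
//   tau_r_X g1'  = -g1 + tau_r_X * sum of presynaptic impulses
// so each presynaptic spike makes g1 jump by the per-edge amplitude
// alpha_hat (source-type pulse size alpha_X * W_YX / N_YX of the target).
// On threshold crossing the voltage is clamped at the reset value for
// tref while the conductances keep evolving.
//
// Spikes are detected at step boundaries; to remove the O(sqrt(dt))
// discrete-monitoring bias of threshold crossings the comparison uses a
// continuity-corrected threshold theta - beta * sd_step with
// beta = -zeta(1/2)/sqrt(2*pi) = 0.5826 (Broadie-Glasserman-Kou) and
// sd_step the white-noise standard deviation accumulated per step.
//
// adjacency in CSR layout by source: edges of source j are
// adj_tgt[adj_ptr[j] .. adj_ptr[j+1]-1] (0-based targets), with per-edge
// g1 jump adj_jump.
// [[Rcpp::export]]
List sim_network_cpp(IntegerVector cell_type, NumericVector theta,
                     NumericVector sigma,
                     IntegerVector adj_ptr, IntegerVector adj_tgt,
                     NumericVector adj_jump,
                     double taum, double EE, double EI, double tref,
                     double vreset,
                     double taur_E, double taud_E, double taur_I, double taud_I,
                     double duration, double dt, int seed,
                     double burn = 0.0, bool correct_threshold = true) {
  const int N = cell_type.size();
  std::mt19937_64 rng((uint64_t) seed);
  std::normal_distribution<double> norm(0.0, 1.0);

  std::vector<double> v(N, 0.0), gE(N, 0.0), gE1(N, 0.0), gI(N, 0.0),
      gI1(N, 0.0), refrac(N, 0.0);
  std::vector<double> sd_step(N), th_eff(N);
  const double bgk = 0.5826;
  for (int i = 0; i < N; ++i) {
    v[i] = vreset;
    sd_step[i] = sigma[i] * std::sqrt(dt / taum);
    th_eff[i] = theta[i] - (correct_threshold ? bgk * sd_step[i] : 0.0);
  }
  std::vector<double> sE(N, 0.0), sE2(N, 0.0), sI(N, 0.0), sI2(N, 0.0);
  long n_acc = 0;

  std::vector<double> spk_t;
  std::vector<int> spk_id;
  std::vector<int> spikers;
  spikers.reserve(N);

  const long nsteps = (long) std::ceil(duration / dt);
  for (long step = 0; step < nsteps; ++step) {
    const double t = (step + 1) * dt;
    spikers.clear();
    for (int i = 0; i < N; ++i) {
      gE[i] += dt * (-gE[i] + gE1[i]) / taud_E;
      gE1[i] += -dt * gE1[i] / taur_E;
      gI[i] += dt * (-gI[i] + gI1[i]) / taud_I;
      gI1[i] += -dt * gI1[i] / taur_I;
      if (refrac[i] > 0.0) {
        refrac[i] -= dt;
        v[i] = vreset;
      } else {
        v[i] += dt * (-v[i] - gE[i] * (v[i] - EE) - gI[i] * (v[i] - EI)) / taum
                + sd_step[i] * norm(rng);
        if (v[i] >= th_eff[i]) {
          spk_t.push_back(t);
          spk_id.push_back(i + 1);
          v[i] = vreset;
          refrac[i] = tref;
          spikers.push_back(i);
        }
      }
    }
    for (int j : spikers) {
      for (int e = adj_ptr[j]; e < adj_ptr[j + 1]; ++e) {
        const int tgt = adj_tgt[e];
        if (cell_type[j] == 0) gE1[tgt] += adj_jump[e];
        else gI1[tgt] += adj_jump[e];
      }
    }
    if (t > burn) {
      for (int i = 0; i < N; ++i) {
        sE[i] += gE[i]; sE2[i] += gE[i] * gE[i];
        sI[i] += gI[i]; sI2[i] += gI[i] * gI[i];
      }
      ++n_acc;
    }
    if ((step & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector mE(N), vE(N), mI(N), vI(N);
  for (int i = 0; i < N; ++i) {
    const double me = sE[i] / n_acc, mi = sI[i] / n_acc;
    mE[i] = me; mI[i] = mi;
    vE[i] = sE2[i] / n_acc - me * me;
    vI[i] = sI2[i] / n_acc - mi * mi;
  }
  return List::create(_["times"] = wrap(spk_t), _["id"] = wrap(spk_id),
                      _["gE_mean"] = mE, _["gE_var"] = vE,
                      _["gI_mean"] = mI, _["gI_var"] = vI);
}

// Reduced effective cell (Ito Euler-Maruyama with multiplicative
// conductance noise); cell layout as in the threshold-integration code.
// Threshold crossings use the same continuity correction as the network
// simulator, with the local diffusion coefficient at threshold.
// [[Rcpp::export]]
NumericVector sim_cell_cpp(NumericVector cell, double duration, double dt,
                           int seed, bool correct_threshold = true) {
  if (cell.size() != 11) stop("cell parameter vector must have length 11");
  const double taum = cell[0], g0 = cell[1], Erev = cell[2], EE = cell[3],
               EI = cell[4], sig2taum = cell[5], s2E = cell[6], s2I = cell[7],
               theta = cell[8], vreset = cell[9], tref = cell[10];
  std::mt19937_64 rng((uint64_t) seed);
  std::normal_distribution<double> norm(0.0, 1.0);
  const double sE = std::sqrt(s2E), sI = std::sqrt(s2I),
               sbg = std::sqrt(sig2taum);
  double v = vreset, refrac = 0.0;
  const double sqdt = std::sqrt(dt);
  // 2 D(theta) = [sigma^2 tau_m + s2E (theta-EE)^2 + s2I (theta-EI)^2]/tau_m^2
  const double twoD = (sig2taum + s2E * (theta - EE) * (theta - EE) +
                       s2I * (theta - EI) * (theta - EI)) / (taum * taum);
  const double th_eff =
      theta - (correct_threshold ? 0.5826 * std::sqrt(twoD * dt) : 0.0);
  std::vector<double> spikes;
  const long nsteps = (long) std::ceil(duration / dt);
  for (long step = 0; step < nsteps; ++step) {
    const double t = (step + 1) * dt;
    if (refrac > 0.0) { refrac -= dt; continue; }
    const double drift = -g0 * (v - Erev) / taum;
    const double noise = (sE * (v - EE) * norm(rng) + sI * (v - EI) * norm(rng)
                          + sbg * norm(rng)) / taum;
    v += drift * dt + noise * sqdt;
    if (v >= th_eff) {
      spikes.push_back(t);
      v = vreset;
      refrac = tref;
    }
    if ((step & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return wrap(spikes);
}

// Second-order alpha synapse driven by a Poisson spike train at rate nu
// (spikes/ms); returns the time-averaged mean and variance of g.
// [[Rcpp::export]]
List sim_poisson_synapse_cpp(double nu, double alpha_hat, double taur,
                             double taud, double duration, double dt,
                             int seed, double burn = 100.0) {
  std::mt19937_64 rng((uint64_t) seed);
  std::poisson_distribution<int> pois(nu * dt);
  double g = 0.0, g1 = 0.0, s = 0.0, s2 = 0.0;
  long n_acc = 0;
  const long nsteps = (long) std::ceil(duration / dt);
  for (long step = 0; step < nsteps; ++step) {
    g += dt * (-g + g1) / taud;
    g1 += -dt * g1 / taur;
    const int k = pois(rng);
    if (k > 0) g1 += alpha_hat * k;
    if ((step + 1) * dt > burn) { s += g; s2 += g * g; ++n_acc; }
    if ((step & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  const double m = s / n_acc;
  return List::create(_["mean"] = m, _["var"] = s2 / n_acc - m * m);
}
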