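// Threshold-integration engine for the effective single-neuron equation
//
//   tau_m dv = -g0 (v - Erev) dt + s_gE (v - EE) dW_E + s_gI (v - EI) dW_I
//              + sqrt(sigma^2 tau_m) dW
//
// interpreted in the Ito sense, giving a Fokker-Planck flux
//   J(v) = F(v) P - d/dv [ D(v) P ],
//   F(v) = -g0 (v - Erev) / tau_m,
//   D(v) = [ sigma^2 tau_m + s2E (v-EE)^2 + s2I (v-EI)^2 ] / (2 tau_m^2).
//
// The stationary density, rate-modulation susceptibilities, first-passage
// moments and the renewal spike-train spectrum are all obtained by
// integrating the flux/density pair backward from the absorbing threshold
// with a per-step exponential (integrating-factor) update.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

struct ECell {
  double taum, g0, Erev, EE, EI, sig2taum, s2E, s2I, theta, vreset, tref;
};

static ECell unpack_cell(const NumericVector& c) {
  if (c.size() != 11) stop("cell parameter vector must have length 11");
  ECell e;
  e.taum = c[0]; e.g0 = c[1]; e.Erev = c[2]; e.EE = c[3]; e.EI = c[4];
  e.sig2taum = c[5]; e.s2E = c[6]; e.s2I = c[7];
  e.theta = c[8]; e.vreset = c[9]; e.tref = c[10];
  if (e.taum <= 0) stop("tau_m must be positive");
  if (e.theta <= e.vreset) stop("threshold must exceed reset");
  return e;
}

static inline double driftF(const ECell& c, double v) {
  return -c.g0 * (v - c.Erev) / c.taum;
}

static inline double diffD(const ECell& c, double v) {
  const double dE = v - c.EE, dI = v - c.EI;
  return (c.sig2taum + c.s2E * dE * dE + c.s2I * dI * dI) /
         (2.0 * c.taum * c.taum);
}

// exponential-integrator step factors over one grid interval of width dv:
// E = exp(-a dv), G = (1 - exp(-a dv)) / a  (limit dv as a -> 0)
static inline void step_factors(double a, double dv, double& E, double& G) {
  double x = a * dv;
  if (x > 700.0) { E = 0.0; G = 1.0 / a; return; }
  if (x < -700.0) x = -700.0;           // barrier overflow guard; detected later
  E = std::exp(-x);
  if (std::fabs(x) < 1e-5) G = dv * (1.0 - 0.5 * x + x * x / 6.0);
  else G = (1.0 - E) / a;
}

struct SteadyOut {
  double rate;
  double dv;
  int kr;
  bool ok;
  std::vector<double> p;   // stationary density scaled by 1/rate
};

static SteadyOut steady_solve(const ECell& c, double vmin, int n) {
  SteadyOut out;
  out.dv = (c.theta - vmin) / (n - 1);
  int kr = (int) std::lround((c.vreset - vmin) / out.dv);
  if (kr < 0) kr = 0;
  if (kr > n - 2) kr = n - 2;
  out.kr = kr;
  std::vector<double> u(n, 0.0);
  for (int k = n - 1; k > 0; --k) {
    const double vm = vmin + (k - 0.5) * out.dv;
    const double a = driftF(c, vm) / diffD(c, vm);
    double E, G;
    step_factors(a, out.dv, E, G);
    const double j = (k - 1 >= kr) ? 1.0 : 0.0;
    u[k - 1] = u[k] * E + j * G;
  }
  out.p.resize(n);
  double I = 0.0;
  bool finite = true;
  for (int k = 0; k < n; ++k) {
    double val = u[k] / diffD(c, vmin + k * out.dv);
    if (!R_finite(val)) { finite = false; val = R_PosInf; }
    else if (val < 0.0) val = 0.0;
    out.p[k] = val;
  }
  if (finite) {
    for (int k = 0; k < n; ++k) I += out.p[k];
    I -= 0.5 * (out.p[0] + out.p[n - 1]);
    I *= out.dv;
  }
  if (!finite || !R_finite(I)) {
    out.rate = 0.0;
    out.ok = false;
  } else {
    out.rate = 1.0 / (I + c.tref);
    out.ok = true;
  }
  return out;
}

// [[Rcpp::export]]
List ti_steady(NumericVector cell, double vmin, int n, bool density = false) {
  ECell c = unpack_cell(cell);
  SteadyOut s = steady_solve(c, vmin, n);
  List out = List::create(_["rate"] = s.rate, _["ok"] = s.ok);
  if (density) {
    NumericVector v(n), P(n);
    for (int k = 0; k < n; ++k) {
      v[k] = vmin + k * s.dv;
      P[k] = s.ok ? s.rate * s.p[k] : NA_REAL;
    }
    out["v"] = v;
    out["density"] = P;
  }
  return out;
}

// first-passage time moments from reset to threshold (backward-equation
// sweeps); ISI = tref + first passage time
// [[Rcpp::export]]
List ti_fpt(NumericVector cell, double vmin, int n) {
  ECell c = unpack_cell(cell);
  const double dv = (c.theta - vmin) / (n - 1);
  int kr = (int) std::lround((c.vreset - vmin) / dv);
  if (kr < 0) kr = 0;
  if (kr > n - 2) kr = n - 2;

  std::vector<double> R1(n, 0.0), T1(n, 0.0), R2(n, 0.0);
  // R1 = -T1' solves R1' = 1/D - (F/D) R1 upward from the reflecting bound
  for (int k = 1; k < n; ++k) {
    const double vm = vmin + (k - 0.5) * dv;
    const double Dm = diffD(c, vm);
    const double a = driftF(c, vm) / Dm;
    double E, G;
    step_factors(a, dv, E, G);
    R1[k] = R1[k - 1] * E + (1.0 / Dm) * G;
  }
  for (int k = n - 2; k >= 0; --k)
    T1[k] = T1[k + 1] + 0.5 * dv * (R1[k] + R1[k + 1]);
  for (int k = 1; k < n; ++k) {
    const double vm = vmin + (k - 0.5) * dv;
    const double Dm = diffD(c, vm);
    const double a = driftF(c, vm) / Dm;
    double E, G;
    step_factors(a, dv, E, G);
    const double src = 2.0 * 0.5 * (T1[k] + T1[k - 1]) / Dm;
    R2[k] = R2[k - 1] * E + src * G;
  }
  double T2r = 0.0;
  for (int k = n - 2; k >= kr; --k)
    T2r += 0.5 * dv * (R2[k] + R2[k + 1]);

  const double m1 = T1[kr];
  const double var = T2r - m1 * m1;
  const double mean = m1 + c.tref;
  bool ok = R_finite(mean) && R_finite(var) && mean > 0.0;
  double cv2 = ok ? var / (mean * mean) : NA_REAL;
  if (ok && cv2 < 0.0) cv2 = 0.0;
  return List::create(_["isi_mean"] = mean,
                      _["isi_var"] = var,
                      _["cv2"] = cv2,
                      _["rate"] = ok ? 1.0 / mean : 0.0,
                      _["ok"] = ok);
}

// one backward sweep of the frequency-domain flux/density pair
//   dj/dv = -i w p (+ flux jump at reset),
//   u = D p + S_D,  du/dv = (F/D) u + (S_F - (F/D) S_D) - j
// channel: -1 none, 0 mean_gE, 1 mean_gI, 2 var_gE, 3 var_gI
static cplx backward_sweep(const ECell& c, double vmin, int n, double omega,
                           cplx jtheta, cplx jump_at_reset,
                           const std::vector<double>* P0, int channel) {
  const double dv = (c.theta - vmin) / (n - 1);
  int kr = (int) std::lround((c.vreset - vmin) / dv);
  if (kr < 0) kr = 0;
  if (kr > n - 2) kr = n - 2;
  const cplx iw(0.0, omega);

  auto F1 = [&](double v) -> double {
    if (channel == 0) return -(v - c.EE) / c.taum;
    if (channel == 1) return -(v - c.EI) / c.taum;
    return 0.0;
  };
  auto D1 = [&](double v) -> double {
    if (channel == 2) { double d = v - c.EE; return d * d / (2.0 * c.taum * c.taum); }
    if (channel == 3) { double d = v - c.EI; return d * d / (2.0 * c.taum * c.taum); }
    return 0.0;
  };
  auto P0node = [&](int k) -> double { return P0 ? (*P0)[k] : 0.0; };

  cplx u = 0.0;                       // at threshold: p = 0 and S_D(theta) = 0
  cplx j = jtheta;
  double vk = c.theta;
  double Dk = diffD(c, vk);
  cplx pk = (u - D1(vk) * P0node(n - 1)) / Dk;

  for (int k = n - 1; k > 0; --k) {
    const double vm = vmin + (k - 0.5) * dv;
    const double Dm = diffD(c, vm);
    const double a = driftF(c, vm) / Dm;
    double E, G;
    step_factors(a, dv, E, G);
    cplx s_m = 0.0;
    if (P0 && channel >= 0) {
      const double P0m = 0.5 * (P0node(k) + P0node(k - 1));
      s_m = (F1(vm) - a * D1(vm)) * P0m;
    }
    const cplx j_half = j + iw * (0.5 * dv) * pk;
    u = u * E + (j_half - s_m) * G;
    const double vk1 = vmin + (k - 1) * dv;
    const cplx pk1 = (u - D1(vk1) * P0node(k - 1)) / diffD(c, vk1);
    j = j + iw * dv * 0.5 * (pk + pk1);
    pk = pk1;
    if (k - 1 == kr) j -= jump_at_reset;
  }
  return j;
}

// susceptibility at omega = 0: stationary perturbation with probability
// (re)normalisation including the refractory fraction
static double susceptibility_zero(const ECell& c, double vmin, int n,
                                  const SteadyOut& s, int channel) {
  const double dv = s.dv;
  auto F1 = [&](double v) -> double {
    if (channel == 0) return -(v - c.EE) / c.taum;
    if (channel == 1) return -(v - c.EI) / c.taum;
    return 0.0;
  };
  auto D1 = [&](double v) -> double {
    if (channel == 2) { double d = v - c.EE; return d * d / (2.0 * c.taum * c.taum); }
    if (channel == 3) { double d = v - c.EI; return d * d / (2.0 * c.taum * c.taum); }
    return 0.0;
  };
  double u = 0.0;
  double integ = 0.0;
  double pk_prev = 0.0;  // p1 at threshold = 0
  for (int k = n - 1; k > 0; --k) {
    const double vm = vmin + (k - 0.5) * dv;
    const double Dm = diffD(c, vm);
    const double a = driftF(c, vm) / Dm;
    double E, G;
    step_factors(a, dv, E, G);
    const double P0m = s.rate * 0.5 * (s.p[k] + s.p[k - 1]);
    const double s_m = (F1(vm) - a * D1(vm)) * P0m;
    u = u * E - s_m * G;
    const double vk1 = vmin + (k - 1) * dv;
    const double pk1 = (u - D1(vk1) * s.rate * s.p[k - 1]) / diffD(c, vk1);
    integ += 0.5 * dv * (pk_prev + pk1);
    pk_prev = pk1;
  }
  return -s.rate * integ;
}

// [[Rcpp::export]]
ComplexVector ti_susceptibility(NumericVector cell, int channel,
                                NumericVector omega, double vmin, int n) {
  ECell c = unpack_cell(cell);
  if (channel < 0 || channel > 3) stop("unknown susceptibility channel");
  const int nw = omega.size();
  ComplexVector out(nw);
  SteadyOut s = steady_solve(c, vmin, n);
  if (!s.ok || s.rate <= 0.0) {
    for (int i = 0; i < nw; ++i) { out[i].r = 0.0; out[i].i = 0.0; }
    return out;
  }
  std::vector<double> P0(n);
  for (int k = 0; k < n; ++k) P0[k] = s.rate * s.p[k];
  for (int i = 0; i < nw; ++i) {
    const double w = omega[i];
    if (w < 0) stop("omega must be nonnegative");
    cplx A;
    if (w == 0.0) {
      A = cplx(susceptibility_zero(c, vmin, n, s, channel), 0.0);
    } else {
      const cplx jump = std::exp(cplx(0.0, -w * c.tref));
      const cplx jA = backward_sweep(c, vmin, n, w, 1.0, jump, nullptr, -1);
      const cplx jB = backward_sweep(c, vmin, n, w, 0.0, 0.0, &P0, channel);
      A = -jB / jA;
    }
    out[i].r = A.real();
    out[i].i = A.imag();
  }
  return out;
}

// uncoupled spike-train power spectrum of the renewal threshold-reset
// process: C0(w) = rate (1 - |F|^2)/|1 - F|^2 with F the Fourier transform
// of the ISI density (first-passage transform delayed by tref); the w = 0
// value is the long-window limit rate * CV^2
// [[Rcpp::export]]
NumericVector ti_spectrum(NumericVector cell, NumericVector omega,
                          double vmin, int n) {
  ECell c = unpack_cell(cell);
  const int nw = omega.size();
  NumericVector out(nw);
  SteadyOut s = steady_solve(c, vmin, n);
  if (!s.ok || s.rate <= 0.0) {
    std::fill(out.begin(), out.end(), 0.0);
    return out;
  }
  List fpt = ti_fpt(cell, vmin, n);
  const double cv2 = as<bool>(fpt["ok"]) ? as<double>(fpt["cv2"]) : 1.0;
  for (int i = 0; i < nw; ++i) {
    const double w = omega[i];
    if (w < 0) stop("omega must be nonnegative");
    if (w == 0.0) { out[i] = s.rate * cv2; continue; }
    const cplx j1 = backward_sweep(c, vmin, n, w, 1.0, 0.0, nullptr, -1);
    const cplx j0 = backward_sweep(c, vmin, n, w, 0.0, 1.0, nullptr, -1);
    const cplx f = -j0 / j1;
    const cplx F = std::exp(cplx(0.0, -w * c.tref)) * f;
    const double den = std::norm(cplx(1.0, 0.0) - F);
    out[i] = s.rate * (1.0 - std::norm(F)) / den;
    if (!R_finite(out[i]) || out[i] < 0.0) out[i] = s.rate * cv2;
  }
  return out;
}
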