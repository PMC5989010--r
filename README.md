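# netlr — linear response theory for heterogeneous recurrent spiking networks

`netlr` computes firing rates and pairwise spike-count correlations in
randomly connected excitatory/inhibitory networks of conductance-based
leaky integrate-and-fire (LIF) neurons, and analyzes when correlations
*increase* or *decrease* with firing rate across a heterogeneous
population. It is aimed at computational neuroscientists who want to
survey many network configurations quickly — the linear-response pipeline
solves a 100-cell network in well under a second, where a direct Monte
Carlo estimate of the same statistics takes minutes — while keeping a
ground-truth simulator in the same package to validate every shortcut.

## The model and the method

Each cell follows a stochastic LIF equation with second-order
alpha-conductance synapses,

    tau_m dv_i/dt = -v_i - g_E,i(t)(v_i - E_E) - g_I,i(t)(v_i - E_I)
                    + sigma_i sqrt(tau_m) xi_i(t),

spiking at a cell-specific threshold theta_i (log-normal across the
population, assigned at equally spaced CDF quantiles) and resetting to 0
after a refractory period. Incoming spikes drive the conductances
through two-stage filters with per-synapse amplitude
`alpha_hat = alpha_X * W_YX / N_YX`, the raw weight divided by the
realized in-degree.

The theory proceeds in three steps:

1. **Effective single cell.** Treating pooled presynaptic spikes as
   Poisson, the conductance mean and variance are
   `<g> = alpha_hat nu tau_r` and
   `Var[g] = (alpha_hat^2 nu tau_r / 2) * tau_r/(tau_r + tau_d)`.
   The voltage equation collapses to an effective leak
   `g0 = 1 + <g_E> + <g_I>`, reversal
   `E_rev = (<g_E> E_E + <g_I> E_I)/g0`, and multiplicative conductance
   noise — a one-dimensional Fokker–Planck problem solved by threshold
   integration (stationary rate, four susceptibility functions
   `A_X(omega)` for the mean/variance of each conductance, and the
   uncoupled spike-train spectrum `C0(omega)`).
2. **Self-consistency and linear response.** Rates and conductance
   moments are iterated to a fixed point. The interaction matrix
   `K_ij(omega) = A_<gX>,i J_ij + A_var_gX,i L_ij` (synaptic filters `J`,
   `L`) then yields the cross-spectrum
   `C = (I - K)^(-1) C0 (I - K*)^(-1)`, whose zero-frequency value gives
   the long-window spike-count correlation
   `rho_ij = C_ij(0)/sqrt(C_ii(0) C_jj(0))`. Expanding the inverse in
   powers of `K` decomposes `rho` into graph motifs: direct connections
   (order 1), common inputs and chains (order 2), and so on.
3. **Correlation susceptibility.** Because inhibitory common input
   dominates, the quantity `S_hat = (dF/dg_I)^2 / F` — computed on a
   reduced firing-rate surface `F(g_I, theta)` with all other parameters
   frozen at population averages — predicts how strongly a cell pair at
   a given operating point converts shared inhibition into correlation.
   Whether `S_hat` rises or falls with `F` along a path through
   `(theta, g_I)` space is decided by the alignment of the gradients of
   `F` and `S_hat`: the fraction of directions with `dS_hat/dF > 0` is
   `(pi - acos(cos_angle))/pi`.

A full Euler–Maruyama simulator of the generative model (with a
continuity-corrected spike threshold) and spike-count window statistics
provide the Monte Carlo ground truth used throughout the test suite.

## Worked example

```r
library(netlr)
net <- build_network(netlr_preset("asynchronous"), seed = 1)
fit <- solve_rates(net)
fit
#> Self-consistent rate solution (converged after 21 iterations, residual 9.4e-07)
#>   mean rate E: 11.00 Hz, I: 47.01 Hz
summary(fit)
#>   over  mean_gE mean_gI sigma_gE sigma_gI sigma_sqrt_taum  E_rev  rate rate_Hz
#> 1    E 0.005486   1.885 0.002735   0.7172           6.325 -0.313 0.011      11
```

The E-cell averages sit at the asynchronous operating point: mean
inhibitory conductance ~1.89, mean excitatory conductance ~0.0055, with
conductance-noise standard deviations 0.72 and 0.0027.

```r
lr <- linear_response(fit)
lr
#> Linear-response correlation analysis (N = 100)
#>   spectral radius of K(0): 0.3926
#>   mean E-E correlation: 0.0065 over 3160 pairs
p <- lr$pairs
motif_regression(p$rho, list(order1 = p$R1, order2 = p$R2,
                             order3 = p$R3, order4 = p$R4))
#> order1 order2 order3 order4
#>  0.002  0.977  0.025  0.006
motif_regression(p$R2, list(E_common = p$E_common, I_common = p$I_common,
                            chain_corr = p$chain_correlating,
                            chain_decorr = p$chain_decorrelating))
#>     E_common     I_common   chain_corr chain_decorr
#>        0.016        0.915        0.026        0.091
```

Second-order motifs explain 98% of the variance in total pairwise
correlation, and among them inhibitory common input dominates (R² =
0.92) — the empirical justification for summarizing the network by its
susceptibility to shared inhibition. The corresponding
susceptibility–rate curve and a Monte Carlo check:

```r
curve <- sf_curve(fit)
attr(curve, "slope_whole")      # -0.042: S_hat falls with rate overall
sim <- simulate(net, seed = 7, duration = 2e4, burn = 1000)
cor(spike_rates(sim), fit$rates)
#> 0.997
```

`rate_surface()`, `path_profile()`, `alignment()` and `sign_map()`
expose the reduced-surface analysis directly, and `run_sweep()` maps
whole `(W_EE, W_IE, sigma_E, sigma_I)` families of networks.

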