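# shared oracles and fixtures for the suite

# fixed deep voltage grid: finite-difference comparisons must share the
# discretization with the quantity they check
tgrid <- voltage_grid(2048, v_min = -6)

# Siegert mean-first-passage quadrature for the additive-noise
# (Ornstein-Uhlenbeck) threshold neuron; independent of the
# threshold-integration path
siegert_rate <- function(cell) {
  stopifnot(cell$sigma_gE2 == 0, cell$sigma_gI2 == 0)
  tau <- cell$tau_m / cell$g0
  sv <- cell$sigma / sqrt(2 * cell$g0)
  f <- function(x) exp(x^2) * (1 + (2 * pnorm(x * sqrt(2)) - 1))
  lo <- (cell$v_reset - cell$E_rev) / (sqrt(2) * sv)
  hi <- (cell$theta - cell$E_rev) / (sqrt(2) * sv)
  T1 <- tau * sqrt(pi) * integrate(f, lo, hi, rel.tol = 1e-11)$value
  1 / (T1 + cell$tau_ref)
}

# a panel of heterogeneous effective cells spanning the operating range
# of the solved networks
random_cells <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) effective_cell(
    mean_gE = runif(1, 0, 0.1), mean_gI = runif(1, 0.8, 2.2),
    sigma_gE2 = runif(1, 0, 0.01), sigma_gI2 = runif(1, 0.1, 0.6),
    sigma = runif(1, 1.0, 1.6), theta = runif(1, 0.8, 1.1)))
}

# central finite differences of the stationary rate wrt the four input
# channels, on a shared grid
rate_derivatives <- function(cell, grid = tgrid,
                             h = c(1e-4, 1e-4, 1e-6, 1e-4)) {
  gE <- (cell$g0 * cell$E_rev - (cell$g0 - 1) * cell$E_I) /
    (cell$E_E - cell$E_I)
  gI <- cell$g0 - 1 - gE
  f <- function(dgE, dgI, dvE, dvI)
    steady_rate(effective_cell(
      mean_gE = gE + dgE, mean_gI = gI + dgI,
      sigma_gE2 = cell$sigma_gE2 + dvE, sigma_gI2 = cell$sigma_gI2 + dvI,
      sigma = cell$sigma, theta = cell$theta, tau_m = cell$tau_m,
      tau_ref = cell$tau_ref, v_reset = cell$v_reset, E_E = cell$E_E,
      E_I = cell$E_I), grid)
  c(mean_gE = (f(h[1], 0, 0, 0) - f(-h[1], 0, 0, 0)) / (2 * h[1]),
    mean_gI = (f(0, h[2], 0, 0) - f(0, -h[2], 0, 0)) / (2 * h[2]),
    var_gE = (f(0, 0, h[3], 0) - f(0, 0, -h[3], 0)) / (2 * h[3]),
    var_gI = (f(0, 0, 0, h[4]) - f(0, 0, 0, -h[4])) / (2 * h[4]))
}

# E-E pair index matrix of a network
ee_pairs <- function(network) {
  isE <- which(network$cell_type == "E")
  pr <- t(utils::combn(isE, 2))
  cbind(pr[, 1], pr[, 2])
}

# wrap explicit spike times as a spike_trains object
as_spike_trains <- function(times, id, duration, n_cells) {
  structure(list(times = times, id = id, duration = duration, dt = NA,
                 seed = NA, n_cells = n_cells,
                 cell_type = rep("E", n_cells), g_moments = NULL),
            class = "spike_trains")
}

# solved presets are reused across tests; cache them per session
preset_fit <- local({
  cache <- list()
  function(name, seed = 1) {
    key <- paste(name, seed)
    if (is.null(cache[[key]])) {
      net <- suppressWarnings(build_network(netlr_preset(name, seed)))
      cache[[key]] <<- solve_rates(net)
    }
    cache[[key]]
  }
})

# frozen surface parameters from a solved fit
frozen_of <- function(fit) {
  ps <- population_summary(fit)
  list(mean_gE = ps$mean_gE, sigma_gE = ps$sigma_gE,
       sigma_gI = ps$sigma_gI,
       sigma = ps$sigma_sqrt_taum / sqrt(fit$network$intrinsic$tau_m),
       gI_center = ps$mean_gI)
}
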