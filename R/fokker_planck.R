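#' Voltage discretization for threshold integration
#'
#' Uniform grid from `v_min` to the cell threshold. By default the lower
#' bound adapts to the cell: eight Ornstein-Uhlenbeck standard deviations
#' below the effective rest (or half a unit below the inhibitory
#' reversal, whichever is lower), deep enough that the truncated
#' stationary mass is negligible at any noise level used here.
#'
#' @param n_points number of grid points (>= 256; default 2^10).
#' @param v_min lower voltage bound; `NULL` = adaptive per cell.
#' @return An object of class `"voltage_grid"`.
#' @export
voltage_grid <- function(n_points = 1024, v_min = NULL) {
  stopifnot(n_points >= 256)
  structure(list(n_points = as.integer(n_points), v_min = v_min),
            class = "voltage_grid")
}

grid_vmin <- function(grid, cell) {
  v_min <- if (is.null(grid$v_min)) {
    # stationary OU variance at the effective rest point
    sv2 <- (cell$sigma^2 +
              (cell$sigma_gE2 * (cell$E_rev - cell$E_E)^2 +
               cell$sigma_gI2 * (cell$E_rev - cell$E_I)^2) / cell$tau_m) /
      (2 * cell$g0)
    min(cell$E_I - 0.5, min(cell$E_rev, cell$v_reset) - 8 * sqrt(sv2))
  } else grid$v_min
  if (v_min >= cell$v_reset)
    stop("voltage grid must start below the reset value")
  # snap the lower bound (slightly deeper) so that the reset voltage lies
  # exactly on a grid node; otherwise the re-injection point moves within
  # a grid cell as parameters vary, leaving a sawtooth in the rate
  n <- grid$n_points
  m <- ceiling((cell$theta - cell$v_reset) / (cell$theta - v_min) * (n - 1))
  dv <- (cell$theta - cell$v_reset) / m
  cell$theta - (n - 1) * dv
}

#' Default frequency grid
#'
#' Zero plus `n` log-spaced angular frequencies (rad/ms).
#'
#' @param n number of positive frequencies.
#' @param lo,hi range of positive frequencies (rad/ms).
#' @return Increasing numeric vector starting at 0.
#' @export
frequency_grid <- function(n = 64, lo = 1e-3, hi = 10) {
  stopifnot(n >= 1, lo > 0, hi > lo)
  c(0, exp(seq(log(lo), log(hi), length.out = n)))
}

#' Stationary firing rate by threshold integration
#'
#' Solves the stationary Fokker-Planck equation of the effective cell
#' (absorbing threshold, re-injection at reset, refractory fraction in the
#' normalization) by backward integration of the scaled density/flux pair
#' from the threshold.
#'
#' @param cell an [effective_cell()].
#' @param grid a [voltage_grid()].
#' @param density if `TRUE`, also return the stationary density.
#' @return Firing rate in spikes/ms, or (with `density = TRUE`) a list
#'   with `rate`, `v` and `density`.
#' @examples
#' cell <- effective_cell(g0 = 2.8353, E_rev = -0.3106, sigma_gI2 = 0.44,
#'                        sigma = 2 / sqrt(2))
#' steady_rate(cell) * 1000  # rate in Hz
#' @export
steady_rate <- function(cell, grid = voltage_grid(), density = FALSE) {
  stopifnot(inherits(cell, "effective_cell"))
  vmin <- grid_vmin(grid, cell)
  res <- ti_steady(cell_vec(cell), vmin, grid$n_points, density)
  if (!res$ok && res$rate != 0)
    stop("threshold integration failed to produce a finite density")
  if (density) res[c("rate", "v", "density")] else res$rate
}

#' Firing-rate susceptibility functions
#'
#' Complex linear gain of the instantaneous firing rate to a small
#' oscillatory perturbation of one of the four input channels of the
#' effective cell: the mean or the variance of the excitatory or
#' inhibitory conductance. At `omega = 0` the susceptibility equals the
#' derivative of the stationary rate with respect to the perturbed
#' parameter (computed analytically from the stationary solver, not by
#' extrapolation).
#'
#' @param cell an [effective_cell()].
#' @param channel one of `"mean_gE"`, `"mean_gI"`, `"var_gE"`, `"var_gI"`.
#' @param omega nonnegative angular frequencies (rad/ms).
#' @param grid a [voltage_grid()].
#' @return Complex vector of susceptibilities, one per frequency (real at
#'   `omega = 0`).
#' @export
susceptibility <- function(cell, channel = c("mean_gE", "mean_gI",
                                             "var_gE", "var_gI"),
                           omega = 0, grid = voltage_grid()) {
  stopifnot(inherits(cell, "effective_cell"), all(omega >= 0))
  channel <- match.arg(channel)
  ch <- match(channel, c("mean_gE", "mean_gI", "var_gE", "var_gI")) - 1L
  vmin <- grid_vmin(grid, cell)
  ti_susceptibility(cell_vec(cell), ch, as.numeric(omega), vmin,
                    grid$n_points)
}

#' Uncoupled spike-train power spectrum
#'
#' Power spectral density of the stationary threshold-reset renewal
#' process, via the Fourier transform of the first-passage (ISI) density;
#' the zero-frequency value is the long-window limit `rate * CV^2` from
#' the first two ISI moments. The spectrum approaches the rate at high
#' frequencies.
#'
#' @param cell an [effective_cell()].
#' @param omega nonnegative angular frequencies (rad/ms).
#' @param grid a [voltage_grid()].
#' @return Nonnegative numeric vector, one value per frequency.
#' @export
power_spectrum_uncoupled <- function(cell, omega = frequency_grid(),
                                     grid = voltage_grid()) {
  stopifnot(inherits(cell, "effective_cell"), all(omega >= 0))
  vmin <- grid_vmin(grid, cell)
  ti_spectrum(cell_vec(cell), as.numeric(omega), vmin, grid$n_points)
}

#' Interspike-interval moments by first-passage integration
#'
#' First two moments of the interspike interval (refractory period plus
#' first passage from reset to threshold) from backward-equation sweeps.
#'
#' @param cell an [effective_cell()].
#' @param grid a [voltage_grid()].
#' @return List with `isi_mean`, `isi_var`, `cv2` and `rate` (= 1/mean).
#' @export
isi_moments <- function(cell, grid = voltage_grid()) {
  stopifnot(inherits(cell, "effective_cell"))
  vmin <- grid_vmin(grid, cell)
  res <- ti_fpt(cell_vec(cell), vmin, grid$n_points)
  res[c("isi_mean", "isi_var", "cv2", "rate")]
}

#' @export
print.effective_cell <- function(x, ...) {
  cat(sprintf("Effective LIF cell: g0 = %.4f, E_rev = %.4f, theta = %.4f\n",
              x$g0, x$E_rev, x$theta))
  cat(sprintf("  sigma_gE = %.4f, sigma_gI = %.4f, sigma*sqrt(tau_m) = %.4f\n",
              sqrt(x$sigma_gE2), sqrt(x$sigma_gI2), x$sigma * sqrt(x$tau_m)))
  invisible(x)
}
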