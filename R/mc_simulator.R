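#' Monte Carlo simulation of the full network
#'
#' Euler-Maruyama integration of the conductance-based LIF network:
#' voltage with threshold-reset and absolute refractory clamp, per-channel
#' second-order alpha-synapse dynamics with per-spike jumps of the
#' target-specific amplitude `alpha_hat`, and independent Gaussian white
#' background noise per cell. Spikes are detected at step boundaries,
#' with a continuity-corrected threshold (shifted by 0.5826 times the
#' per-step noise standard deviation) that removes the `O(sqrt(dt))`
#' discrete-monitoring bias of first-passage times.
#'
#' @param object a `"netlr_network"`.
#' @param nsim unused (single realization; part of the [stats::simulate()]
#'   generic signature).
#' @param seed integer RNG seed for the simulation noise.
#' @param duration simulated time (ms).
#' @param dt time step (ms); must not exceed a tenth of the fastest
#'   synaptic rise time.
#' @param burn initial transient excluded from the conductance-moment
#'   accumulators (spikes during the burn-in are still returned).
#' @param ... unused.
#' @return An object of class `"spike_trains"`: `times` (ms), `id`
#'   (1-based cell index), `duration`, `dt`, `seed`, `n_cells`,
#'   `cell_type`, and `g_moments` (per-cell time-averaged mean/variance of
#'   the simulated conductances after burn-in).
#' @export
simulate.netlr_network <- function(object, nsim = 1, seed = 1,
                                   duration = 10000, dt = 0.01,
                                   burn = 500, ...) {
  syn <- object$synapses
  if (dt > 0.1 * min(syn$tau_r_E, syn$tau_r_I))
    stop("dt must be at most a tenth of the fastest synaptic rise time")
  if (duration <= burn) stop("duration must exceed the burn-in")
  intr <- object$intrinsic
  # CSR by source: edges j -> i
  adj <- object$adjacency
  N <- object$N
  tgt_list <- lapply(seq_len(N), function(j) which(adj[, j] > 0))
  deg <- lengths(tgt_list)
  adj_ptr <- c(0L, cumsum(deg))
  adj_tgt <- as.integer(unlist(tgt_list, use.names = FALSE)) - 1L
  src_type <- rep(match(object$cell_type, c("E", "I")), deg)
  tgt_idx <- unlist(tgt_list, use.names = FALSE)
  adj_jump <- ifelse(src_type == 1, object$alpha_hat[tgt_idx, "E"],
                     object$alpha_hat[tgt_idx, "I"])
  if (length(adj_jump) == 0) adj_jump <- numeric(0)
  sigma <- ifelse(object$cell_type == "E", intr$sigma_E, intr$sigma_I)

  res <- sim_network_cpp(
    cell_type = match(object$cell_type, c("E", "I")) - 1L,
    theta = object$theta, sigma = sigma,
    adj_ptr = as.integer(adj_ptr), adj_tgt = adj_tgt,
    adj_jump = as.numeric(adj_jump),
    taum = intr$tau_m, EE = intr$E_E, EI = intr$E_I,
    tref = intr$tau_ref, vreset = intr$v_reset,
    taur_E = syn$tau_r_E, taud_E = syn$tau_d_E,
    taur_I = syn$tau_r_I, taud_I = syn$tau_d_I,
    duration = duration, dt = dt, seed = as.integer(seed), burn = burn)

  structure(list(times = res$times, id = res$id, duration = duration,
                 dt = dt, seed = seed, n_cells = N,
                 cell_type = object$cell_type,
                 g_moments = data.frame(gE_mean = res$gE_mean,
                                        gE_var = res$gE_var,
                                        gI_mean = res$gI_mean,
                                        gI_var = res$gI_var)),
            class = "spike_trains")
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("Spike trains: %d cells, %.1f s, %d spikes (dt = %g ms)\n",
              x$n_cells, x$duration / 1000, length(x$times), x$dt))
  invisible(x)
}

#' Per-cell firing rates of a simulation
#'
#' @param spikes a `"spike_trains"` object.
#' @param from count spikes from this time (ms), excluding the transient.
#' @return Rates in spikes/ms, one per cell.
#' @export
spike_rates <- function(spikes, from = 500) {
  stopifnot(inherits(spikes, "spike_trains"))
  keep <- spikes$times > from
  counts <- tabulate(spikes$id[keep], nbins = spikes$n_cells)
  counts / (spikes$duration - from)
}

#' Spike-count statistics in time windows
#'
#' Counts spikes in windows of length `T_win` (disjoint by default),
#' returning unbiased variances, covariances and the Pearson spike-count
#' correlation per pair. Pairs involving a zero-variance cell are `NA`.
#'
#' @param spikes a `"spike_trains"` object.
#' @param T_win window length (ms).
#' @param from start of the counting interval (ms).
#' @param stride spacing between window starts; defaults to `T_win`
#'   (disjoint windows). Smaller values give overlapping windows.
#' @return An object of class `"count_statistics"`: `T_win`, `n_windows`,
#'   per-cell `mean` and `var`, matrices `cov` and `rho`.
#' @export
count_statistics <- function(spikes, T_win = 200, from = 500,
                             stride = NULL) {
  stopifnot(inherits(spikes, "spike_trains"), T_win > 0)
  if (is.null(stride)) stride <- T_win
  span <- spikes$duration - from
  if (span < 20 * T_win)
    warning("fewer than 20 windows available; count statistics will be noisy")
  starts <- seq(from, spikes$duration - T_win, by = stride)
  nw <- length(starts)
  counts <- matrix(0L, nw, spikes$n_cells)
  keep <- spikes$times > from
  tms <- spikes$times[keep]
  ids <- spikes$id[keep]
  if (stride == T_win) {
    w <- floor((tms - from) / T_win) + 1
    ok <- w >= 1 & w <= nw
    flat <- tabulate((ids[ok] - 1L) * nw + w[ok], nbins = nw * spikes$n_cells)
    counts <- matrix(flat, nw, spikes$n_cells)
  } else {
    for (wi in seq_len(nw)) {
      inw <- tms > starts[wi] & tms <= starts[wi] + T_win
      counts[wi, ] <- tabulate(ids[inw], nbins = spikes$n_cells)
    }
  }
  cv <- stats::cov(counts)
  v <- diag(cv)
  s <- sqrt(v)
  rho <- cv / outer(s, s)
  rho[, v == 0] <- NA_real_
  rho[v == 0, ] <- NA_real_
  diag(rho)[v > 0] <- 1
  structure(list(T_win = T_win, n_windows = nw, mean = colMeans(counts),
                 var = v, cov = cv, rho = rho),
            class = "count_statistics")
}

#' @export
print.count_statistics <- function(x, ...) {
  cat(sprintf("Spike-count statistics: T = %g ms, %d windows\n",
              x$T_win, x$n_windows))
  cat(sprintf("  mean Fano factor: %.3f\n", mean(x$var / pmax(x$mean, 1e-12))))
  invisible(x)
}

#' Monte Carlo simulation of a single effective cell
#'
#' Ito Euler-Maruyama integration of the reduced voltage equation with
#' multiplicative conductance noise; used to validate the threshold
#' integration engine.
#'
#' @param cell an [effective_cell()].
#' @param duration simulated time (ms).
#' @param dt time step (ms).
#' @param seed integer RNG seed.
#' @return A `"spike_trains"` object with one cell.
#' @export
simulate_cell <- function(cell, duration = 1e5, dt = 0.01, seed = 1) {
  stopifnot(inherits(cell, "effective_cell"))
  tms <- sim_cell_cpp(cell_vec(cell), duration, dt, as.integer(seed))
  structure(list(times = tms, id = rep(1L, length(tms)),
                 duration = duration, dt = dt, seed = seed, n_cells = 1L,
                 cell_type = "E",
                 g_moments = NULL),
            class = "spike_trains")
}

#' Monte Carlo moments of a Poisson-driven alpha synapse
#'
#' Long-run mean and variance of the conductance of one second-order
#' alpha synapse driven by a homogeneous Poisson spike train; the
#' stationary values are `alpha_hat * nu * tau_r` and
#' `alpha_hat^2 * nu * tau_r^2 / (2 (tau_r + tau_d))`.
#'
#' @param nu input rate (spikes/ms).
#' @param alpha_hat per-spike jump of the auxiliary variable.
#' @param tau_r,tau_d synapse time constants (ms).
#' @param duration,dt,seed simulation controls.
#' @return List with `mean` and `var`.
#' @export
poisson_synapse_moments <- function(nu, alpha_hat, tau_r, tau_d,
                                    duration = 2e5, dt = 0.01, seed = 1) {
  stopifnot(nu >= 0, tau_r > 0, tau_d > 0)
  sim_poisson_synapse_cpp(nu, alpha_hat, tau_r, tau_d, duration, dt,
                          as.integer(seed))
}
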