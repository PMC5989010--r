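#' Deterministic log-normal threshold sample
#'
#' Spiking thresholds are drawn from a log-normal distribution with mean 1
#' and variance `exp(cv_param^2) - 1` (log-scale location `-cv_param^2/2`,
#' scale `cv_param`), not at random but at `n` equally spaced CDF values in
#' `[cdf_lo, cdf_hi]`. This pins the heterogeneity exactly at moderate
#' population sizes: the same `n` always yields the same thresholds.
#'
#' @param n number of thresholds.
#' @param cv_param log-scale standard deviation; 0 gives all-equal
#'   thresholds of 1.
#' @param cdf_lo,cdf_hi CDF range (0 < lo <= hi < 1). With `n = 1` the
#'   midpoint 0.5 (the median) is used.
#' @return Increasing numeric vector of length `n`.
#' @examples
#' sample_thresholds(19)          # the default heterogeneous population
#' sample_thresholds(1)           # the log-normal median
#' @export
sample_thresholds <- function(n, cv_param = 0.2, cdf_lo = 0.05,
                              cdf_hi = 0.95) {
  stopifnot(n >= 1)
  if (!(cdf_lo > 0 && cdf_lo <= cdf_hi && cdf_hi < 1))
    stop("invalid CDF bounds: need 0 < cdf_lo <= cdf_hi < 1")
  p <- if (n == 1) 0.5 else cdf_lo + (cdf_hi - cdf_lo) * (seq_len(n) - 1) / (n - 1)
  mu <- -cv_param^2 / 2
  qlnorm(p, meanlog = mu, sdlog = cv_param)
}

#' Build a heterogeneous E/I network
#'
#' Samples an Erdos-Renyi style directed adjacency (independent Bernoulli
#' per ordered pair at the type-to-type connection probability, no
#' self-connections), assigns log-normal thresholds separately to the E
#' and I populations via [sample_thresholds()], and records the realized
#' per-cell in-degrees that normalize the raw synaptic weights.
#'
#' Cells are ordered E first (1..N_E) then I. `adjacency[i, j] = 1` means
#' a connection from source j onto target i.
#'
#' @param config a [netlr_config()] object (or preset).
#' @param seed optional integer overriding `config$seed`.
#' @return An object of class `"netlr_network"`: list with `N_E`, `N_I`,
#'   `cell_type` (`"E"`/`"I"`), `theta`, `adjacency`, `in_degree`
#'   (N x 2 matrix, columns E and I), `alpha_hat` (N x 2 matrix of
#'   per-synapse pulse amplitudes `alpha_X * W_YX / N_YX(i)`; 0 where the
#'   in-degree is 0), plus the configuration components.
#' @export
build_network <- function(config = netlr_config(), seed = NULL) {
  stopifnot(inherits(config, "netlr_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  N_E <- config$N_E; N_I <- config$N_I
  N <- N_E + N_I
  cell_type <- rep(c("E", "I"), c(N_E, N_I))

  p <- config$coupling$p_conn
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  pm <- matrix(p[cell_type, cell_type], N, N)  # [target, source]
  adj <- matrix(rbinom(N * N, 1L, pm), N, N)
  diag(adj) <- 0L

  theta <- c(sample_thresholds(N_E, config$theta_cv, config$theta_cdf_lo,
                               config$theta_cdf_hi),
             sample_thresholds(N_I, config$theta_cv, config$theta_cdf_lo,
                               config$theta_cdf_hi))
  stopifnot(all(theta > config$intrinsic$v_reset))

  isE <- cell_type == "E"
  in_degree <- cbind(E = rowSums(adj[, isE, drop = FALSE]),
                     I = rowSums(adj[, !isE, drop = FALSE]))

  W <- config$coupling$W
  syn <- config$synapses
  alpha_hat <- matrix(0, N, 2, dimnames = list(NULL, c("E", "I")))
  for (X in c("E", "I")) {
    aX <- if (X == "E") syn$alpha_E else syn$alpha_I
    nin <- in_degree[, X]
    w <- W[cbind(cell_type, X)]
    ok <- nin > 0
    alpha_hat[ok, X] <- aX * w[ok] / nin[ok]
    if (any(!ok & w > 0))
      warning(sprintf("%d cell(s) have zero %s in-degree with nonzero weight; %s input dropped for them",
                      sum(!ok & w > 0), X, X))
  }

  structure(list(N_E = N_E, N_I = N_I, N = N, cell_type = cell_type,
                 theta = theta, adjacency = adj, in_degree = in_degree,
                 alpha_hat = alpha_hat, intrinsic = config$intrinsic,
                 synapses = config$synapses, coupling = config$coupling,
                 seed = config$seed, config = config),
            class = "netlr_network")
}

#' Construct a network from an explicit adjacency matrix
#'
#' Used for small analytic fixtures where the motif geometry must be
#' exact rather than sampled.
#'
#' @param adjacency N x N 0/1 matrix, `adjacency[i, j] = 1` for j -> i.
#' @param cell_type character vector of `"E"`/`"I"` labels.
#' @param theta per-cell thresholds.
#' @param config a [netlr_config()] supplying intrinsic/synapse/coupling
#'   parameters (its sizes are ignored).
#' @return A `"netlr_network"` object.
#' @export
network_from_adjacency <- function(adjacency, cell_type, theta,
                                   config = netlr_config()) {
  N <- length(cell_type)
  adjacency <- matrix(as.integer(adjacency), N, N)
  stopifnot(nrow(adjacency) == N, length(theta) == N,
            all(diag(adjacency) == 0), all(cell_type %in% c("E", "I")),
            all(theta > config$intrinsic$v_reset))
  isE <- cell_type == "E"
  in_degree <- cbind(E = rowSums(adjacency[, isE, drop = FALSE]),
                     I = rowSums(adjacency[, !isE, drop = FALSE]))
  W <- config$coupling$W
  syn <- config$synapses
  alpha_hat <- matrix(0, N, 2, dimnames = list(NULL, c("E", "I")))
  for (X in c("E", "I")) {
    aX <- if (X == "E") syn$alpha_E else syn$alpha_I
    nin <- in_degree[, X]
    ok <- nin > 0
    alpha_hat[ok, X] <- aX * W[cbind(cell_type[ok], X)] / nin[ok]
  }
  structure(list(N_E = sum(isE), N_I = sum(!isE), N = N,
                 cell_type = cell_type, theta = theta, adjacency = adjacency,
                 in_degree = in_degree, alpha_hat = alpha_hat,
                 intrinsic = config$intrinsic, synapses = config$synapses,
                 coupling = config$coupling, seed = config$seed,
                 config = config),
            class = "netlr_network")
}

#' @export
print.netlr_network <- function(x, ...) {
  cat(sprintf("LIF network: %d E + %d I cells (seed %d)\n",
              x$N_E, x$N_I, x$seed))
  cat(sprintf("  thresholds in [%.3f, %.3f]; %d directed connections\n",
              min(x$theta), max(x$theta), sum(x$adjacency)))
  cat(sprintf("  mean in-degree E: %.1f, I: %.1f\n",
              mean(x$in_degree[, "E"]), mean(x$in_degree[, "I"])))
  invisible(x)
}

#' Conductance mean and variance from presynaptic firing rates
#'
#' Treating the pooled type-X presynaptic spikes of each cell as a Poisson
#' stream at the summed rate `nu_X,i`, the stationary conductance moments
#' of the second-order alpha synapse are
#' \deqn{\langle g \rangle = \hat\alpha \nu \tau_r, \qquad
#'       \mathrm{Var}[g] = \tfrac12 \hat\alpha^2 \nu \tau_r
#'       \frac{\tau_r}{\tau_r + \tau_d},}
#' with `alpha_hat` the per-synapse pulse amplitude of the target cell.
#'
#' @param network a `"netlr_network"`.
#' @param rates per-cell firing rates in spikes/ms (nonnegative).
#' @return A data.frame with per-cell columns `nu_E`, `nu_I`, `mean_gE`,
#'   `var_gE`, `mean_gI`, `var_gI`.
#' @export
conductance_moments <- function(network, rates) {
  stopifnot(inherits(network, "netlr_network"),
            length(rates) == network$N)
  if (any(rates < 0)) stop("firing rates must be nonnegative")
  isE <- network$cell_type == "E"
  nu_E <- as.vector(network$adjacency[, isE, drop = FALSE] %*% rates[isE])
  nu_I <- as.vector(network$adjacency[, !isE, drop = FALSE] %*% rates[!isE])
  syn <- network$synapses
  aE <- network$alpha_hat[, "E"]; aI <- network$alpha_hat[, "I"]
  data.frame(
    nu_E = nu_E, nu_I = nu_I,
    mean_gE = aE * nu_E * syn$tau_r_E,
    var_gE = 0.5 * aE^2 * nu_E * syn$tau_r_E *
      syn$tau_r_E / (syn$tau_r_E + syn$tau_d_E),
    mean_gI = aI * nu_I * syn$tau_r_I,
    var_gI = 0.5 * aI^2 * nu_I * syn$tau_r_I *
      syn$tau_r_I / (syn$tau_r_I + syn$tau_d_I))
}

#' Effective single-cell parameters
#'
#' The effective time-constant reduction lumps the mean synaptic
#' conductances into an effective leak `g0 = 1 + <g_E> + <g_I>` and
#' reversal `E_rev = (<g_E> E_E + <g_I> E_I) / g0`, and carries the
#' conductance fluctuations as multiplicative noise variances.
#'
#' @param network a `"netlr_network"`.
#' @param moments output of [conductance_moments()].
#' @return A data.frame with per-cell columns `g0`, `E_rev`, `sigma_gE2`,
#'   `sigma_gI2`, `sigma`, `theta`.
#' @export
effective_parameters <- function(network, moments) {
  intr <- network$intrinsic
  g0 <- 1 + moments$mean_gE + moments$mean_gI
  E_rev <- (moments$mean_gE * intr$E_E + moments$mean_gI * intr$E_I) / g0
  sigma <- ifelse(network$cell_type == "E", intr$sigma_E, intr$sigma_I)
  data.frame(g0 = g0, E_rev = E_rev,
             sigma_gE2 = moments$var_gE, sigma_gI2 = moments$var_gI,
             sigma = sigma, theta = network$theta)
}

#' Construct a single effective cell
#'
#' The reduced stochastic voltage equation
#' \deqn{\tau_m dv = -g_0 (v - E_{rev}) dt
#'   + \sigma_{g_E} (v - E_E) dW_E + \sigma_{g_I} (v - E_I) dW_I
#'   + \sigma \sqrt{\tau_m}\, dW}
#' with threshold `theta`, reset `v_reset` and refractory period
#' `tau_ref`. `mean_gE`/`mean_gI` may be given instead of `g0`/`E_rev`.
#'
#' @param g0 effective leak conductance (>= 1); computed from the mean
#'   conductances when `mean_gE`/`mean_gI` are supplied.
#' @param E_rev effective reversal potential.
#' @param mean_gE,mean_gI mean synaptic conductances (alternative input).
#' @param sigma_gE2,sigma_gI2 conductance-noise variances.
#' @param sigma background noise magnitude.
#' @param theta spiking threshold.
#' @param tau_m,tau_ref,v_reset,E_E,E_I intrinsic constants.
#' @return An object of class `"effective_cell"`.
#' @export
effective_cell <- function(g0 = NULL, E_rev = NULL, mean_gE = NULL,
                           mean_gI = NULL, sigma_gE2 = 0, sigma_gI2 = 0,
                           sigma = 2 / sqrt(2), theta = 1, tau_m = 20,
                           tau_ref = 2, v_reset = 0, E_E = 6.5, E_I = -0.5) {
  if (is.null(g0)) {
    stopifnot(!is.null(mean_gE), !is.null(mean_gI),
              mean_gE >= 0, mean_gI >= 0)
    g0 <- 1 + mean_gE + mean_gI
    E_rev <- (mean_gE * E_E + mean_gI * E_I) / g0
  }
  stopifnot(g0 >= 1, sigma_gE2 >= 0, sigma_gI2 >= 0, sigma >= 0,
            theta > v_reset)
  structure(list(tau_m = tau_m, g0 = g0, E_rev = E_rev, E_E = E_E,
                 E_I = E_I, sigma = sigma, sigma_gE2 = sigma_gE2,
                 sigma_gI2 = sigma_gI2, theta = theta, v_reset = v_reset,
                 tau_ref = tau_ref),
            class = "effective_cell")
}

# parameter vector layout consumed by the C++ threshold-integration code
cell_vec <- function(cell) {
  c(cell$tau_m, cell$g0, cell$E_rev, cell$E_E, cell$E_I,
    cell$sigma^2 * cell$tau_m, cell$sigma_gE2, cell$sigma_gI2,
    cell$theta, cell$v_reset, cell$tau_ref)
}

# effective cell for row i of an effective_parameters() data.frame
cell_from_row <- function(network, eff, i) {
  intr <- network$intrinsic
  effective_cell(g0 = eff$g0[i], E_rev = eff$E_rev[i],
                 sigma_gE2 = eff$sigma_gE2[i], sigma_gI2 = eff$sigma_gI2[i],
                 sigma = eff$sigma[i], theta = eff$theta[i],
                 tau_m = intr$tau_m, tau_ref = intr$tau_ref,
                 v_reset = intr$v_reset, E_E = intr$E_E, E_I = intr$E_I)
}
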