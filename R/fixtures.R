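#' Deterministic test-network fixtures
#'
#' Small networks with exactly known motif geometry, for fast analytic
#' checks:
#' \describe{
#'   \item{uncoupled_pair}{two E cells, no edges.}
#'   \item{common_I_source}{one I cell projecting onto two E cells: the
#'     pure common-inhibition motif.}
#'   \item{ee_chain}{three E cells in a chain 1 -> 2 -> 3.}
#'   \item{two_by_two_analytic}{two E cells with a single directed edge
#'     1 -> 2 (closed-form cross-spectrum).}
#'   \item{mini_asyn}{8 E + 2 I cells, all-to-all connected (no
#'     autapses), with the raw weights scaled by the ratio of mini to
#'     full-size in-degrees so that the per-synapse pulse amplitudes
#'     `alpha_hat` match the reference asynchronous network; noise and
#'     kinetics unchanged. Fully deterministic.}
#' }
#' All fixtures share the standard intrinsic and synaptic constants, so
#' analytic values (e.g. the 1/12 variance-filter ratio of the E synapse
#' at unit amplitude) remain valid.
#'
#' @param name fixture name.
#' @param seed connectivity seed (only `mini_asyn` samples connectivity).
#' @return A `"netlr_network"` object.
#' @export
make_fixture <- function(name = c("uncoupled_pair", "common_I_source",
                                  "ee_chain", "two_by_two_analytic",
                                  "mini_asyn"),
                         seed = 1) {
  name <- match.arg(name)
  base <- netlr_config(seed = seed, name = name)
  if (name == "mini_asyn") {
    # all-to-all in-degrees at 8E + 2I vs the expected in-degrees of the
    # 80E + 20I reference network (E cells: 32 E / 7 I; I cells: 16 E / 8 I)
    cfg <- netlr_config(
      N_E = 8, N_I = 2, intrinsic = base$intrinsic,
      synapses = base$synapses,
      coupling = coupling_spec(
        W_EE = 0.5 * 7 / 32, W_EI = 10 * 2 / 7,
        W_IE = 5 * 8 / 16, W_II = 5 * 1 / 8,
        p_EE = 1, p_EI = 1, p_IE = 1, p_II = 1),
      seed = seed, name = name)
    N <- 10
    adj <- matrix(1L, N, N); diag(adj) <- 0L
    theta <- c(sample_thresholds(8, cfg$theta_cv, cfg$theta_cdf_lo,
                                 cfg$theta_cdf_hi),
               sample_thresholds(2, cfg$theta_cv, 0.25, 0.75))
    return(network_from_adjacency(adj, rep(c("E", "I"), c(8, 2)), theta,
                                  cfg))
  }
  spec <- switch(name,
    uncoupled_pair = list(type = c("E", "E"), edges = NULL),
    common_I_source = list(type = c("I", "E", "E"),
                           edges = rbind(c(1, 2), c(1, 3))),
    ee_chain = list(type = c("E", "E", "E"),
                    edges = rbind(c(1, 2), c(2, 3))),
    two_by_two_analytic = list(type = c("E", "E"),
                               edges = rbind(c(1, 2))))
  N <- length(spec$type)
  base$N_E <- sum(spec$type == "E")
  base$N_I <- max(1L, sum(spec$type == "I"))
  base$name <- name
  adj <- matrix(0L, N, N)
  if (!is.null(spec$edges))
    adj[cbind(spec$edges[, 2], spec$edges[, 1])] <- 1L  # [target, source]
  theta <- sample_thresholds(N, base$theta_cv, 0.25, 0.75)
  network_from_adjacency(adj, spec$type, theta, base)
}
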