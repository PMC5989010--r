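#' Intrinsic single-cell parameters
#'
#' Membrane and background-noise constants shared by all cells of the
#' network. Voltages are dimensionless (threshold near 1); time is in ms.
#'
#' @param tau_m membrane time constant (ms).
#' @param E_E,E_I excitatory/inhibitory synaptic reversal potentials
#'   (dimensionless voltage); must bracket the reset value.
#' @param tau_ref absolute refractory period (ms).
#' @param v_reset reset voltage.
#' @param sigma_E,sigma_I background white-noise magnitude for E and I
#'   cells (enters the voltage equation as `sigma * sqrt(tau_m) * xi(t)`).
#' @return An object of class `"intrinsic_params"`.
#' @export
intrinsic_params <- function(tau_m = 20, E_E = 6.5, E_I = -0.5, tau_ref = 2,
                             v_reset = 0, sigma_E = 2 / sqrt(2),
                             sigma_I = 3 / sqrt(2)) {
  stopifnot(tau_m > 0, tau_ref >= 0, E_I < v_reset, v_reset < E_E,
            sigma_E >= 0, sigma_I >= 0)
  structure(list(tau_m = tau_m, E_E = E_E, E_I = E_I, tau_ref = tau_ref,
                 v_reset = v_reset, sigma_E = sigma_E, sigma_I = sigma_I),
            class = "intrinsic_params")
}

#' Second-order alpha-synapse kinetics
#'
#' Each synaptic channel is a cascade of two first-order filters with rise
#' time `tau_r` and decay time `tau_d`; a presynaptic spike of unit weight
#' deposits a pulse of amplitude `alpha` on the auxiliary variable.
#'
#' @param alpha_E,alpha_I pulse amplitudes (dimensionless).
#' @param tau_r_E,tau_d_E,tau_r_I,tau_d_I rise/decay time constants (ms).
#' @return An object of class `"synapse_kinetics"`.
#' @export
synapse_kinetics <- function(alpha_E = 1, alpha_I = 2, tau_r_E = 1,
                             tau_d_E = 5, tau_r_I = 2, tau_d_I = 10) {
  stopifnot(alpha_E > 0, alpha_I > 0, tau_r_E > 0, tau_d_E > 0,
            tau_r_I > 0, tau_d_I > 0)
  structure(list(alpha_E = alpha_E, alpha_I = alpha_I,
                 tau_r_E = tau_r_E, tau_d_E = tau_d_E,
                 tau_r_I = tau_r_I, tau_d_I = tau_d_I),
            class = "synapse_kinetics")
}

#' Coupling strengths and connection probabilities
#'
#' Raw synaptic weights `W[Y, X]` for X -> Y connections (target type in
#' rows, source type in columns) and the corresponding Bernoulli connection
#' probabilities. The raw weight is divided by the realized number of
#' incoming X -> Y connections of each target cell, so `W = 1` corresponds
#' to presynaptic drive at the average population rate in an all-to-all
#' homogeneous network. Signs enter through the reversal potentials, so
#' weights are nonnegative.
#'
#' @param W_EE,W_EI,W_IE,W_II raw weights; `W_EI` is the strength of
#'   I -> E connections (first index = target).
#' @param p_EE,p_EI,p_IE,p_II connection probabilities, same indexing.
#' @return An object of class `"coupling_spec"` with 2x2 matrices `W` and
#'   `p_conn` (dimnames `c("E","I")` for target and source).
#' @export
coupling_spec <- function(W_EE = 0.5, W_EI = 10, W_IE = 5, W_II = 5,
                          p_EE = 0.40, p_EI = 0.35, p_IE = 0.20, p_II = 0.40) {
  W <- matrix(c(W_EE, W_IE, W_EI, W_II), 2, 2,
              dimnames = list(target = c("E", "I"), source = c("E", "I")))
  p <- matrix(c(p_EE, p_IE, p_EI, p_II), 2, 2,
              dimnames = list(target = c("E", "I"), source = c("E", "I")))
  stopifnot(all(W >= 0), all(p >= 0), all(p <= 1))
  structure(list(W = W, p_conn = p), class = "coupling_spec")
}

#' Assemble a full network configuration
#'
#' Bundles population sizes, intrinsic parameters, synapse kinetics,
#' coupling and the threshold-heterogeneity settings into a single
#' configuration object that [build_network()] consumes.
#'
#' @param N_E,N_I numbers of excitatory and inhibitory cells.
#' @param intrinsic an [intrinsic_params()] object.
#' @param synapses a [synapse_kinetics()] object.
#' @param coupling a [coupling_spec()] object.
#' @param theta_cv log-scale parameter of the log-normal threshold
#'   distribution (mean 1, variance `exp(theta_cv^2) - 1`).
#' @param theta_cdf_lo,theta_cdf_hi CDF range over which thresholds are
#'   placed at equally spaced quantiles.
#' @param seed integer seed for the connectivity realization.
#' @param name optional label.
#' @return An object of class `"netlr_config"`.
#' @export
netlr_config <- function(N_E = 80, N_I = 20, intrinsic = intrinsic_params(),
                         synapses = synapse_kinetics(),
                         coupling = coupling_spec(), theta_cv = 0.2,
                         theta_cdf_lo = 0.05, theta_cdf_hi = 0.95,
                         seed = 1, name = "custom") {
  stopifnot(N_E >= 1, N_I >= 1,
            inherits(intrinsic, "intrinsic_params"),
            inherits(synapses, "synapse_kinetics"),
            inherits(coupling, "coupling_spec"))
  structure(list(N_E = as.integer(N_E), N_I = as.integer(N_I),
                 intrinsic = intrinsic, synapses = synapses,
                 coupling = coupling, theta_cv = theta_cv,
                 theta_cdf_lo = theta_cdf_lo, theta_cdf_hi = theta_cdf_hi,
                 seed = as.integer(seed), name = name),
            class = "netlr_config")
}

#' Packaged network presets
#'
#' Two reference parameter sets: `"asynchronous"` (weak recurrent
#' excitation, strong background noise) and `"strong_asynchronous"`
#' (strong recurrent excitation, weaker noise). They differ in
#' `W_EE` (0.5 vs 9), `W_IE` (5 vs 8) and the background noise
#' (`sigma_E` = 2/sqrt(2) vs 1.5/sqrt(2); `sigma_I` = 3/sqrt(2) vs
#' 2.5/sqrt(2)); all other parameters are shared.
#'
#' @param name preset name.
#' @param seed connectivity seed to store in the configuration.
#' @return A [netlr_config()] object.
#' @export
netlr_preset <- function(name = c("asynchronous", "strong_asynchronous"),
                         seed = 1) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "netlr")
  cfg <- read_config(path)
  cfg$seed <- as.integer(seed)
  cfg
}

#' Read a network configuration from a YAML file
#'
#' The file holds a flat block of named scalars (`tau_m`, `E_E`, `E_I`,
#' `tau_ref`, `alpha_E`, ..., `W_EE`, `sigma_E`, `N_E`, `theta_cv`,
#' `seed`, ...) plus a `p_conn` block with `EE`, `EI`, `IE`, `II`
#' probabilities; see the packaged presets in `inst/extdata` for the
#' complete key list.
#'
#' @param path file path.
#' @return A [netlr_config()] object.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  get_or <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
  netlr_config(
    N_E = get_or("N_E", 80), N_I = get_or("N_I", 20),
    intrinsic = intrinsic_params(
      tau_m = get_or("tau_m", 20), E_E = get_or("E_E", 6.5),
      E_I = get_or("E_I", -0.5), tau_ref = get_or("tau_ref", 2),
      v_reset = get_or("v_reset", 0),
      sigma_E = get_or("sigma_E", 2 / sqrt(2)),
      sigma_I = get_or("sigma_I", 3 / sqrt(2))),
    synapses = synapse_kinetics(
      alpha_E = get_or("alpha_E", 1), alpha_I = get_or("alpha_I", 2),
      tau_r_E = get_or("tau_r_E", 1), tau_d_E = get_or("tau_d_E", 5),
      tau_r_I = get_or("tau_r_I", 2), tau_d_I = get_or("tau_d_I", 10)),
    coupling = coupling_spec(
      W_EE = get_or("W_EE", 0.5), W_EI = get_or("W_EI", 10),
      W_IE = get_or("W_IE", 5), W_II = get_or("W_II", 5),
      p_EE = y$p_conn$EE, p_EI = y$p_conn$EI,
      p_IE = y$p_conn$IE, p_II = y$p_conn$II),
    theta_cv = get_or("theta_cv", 0.2),
    theta_cdf_lo = get_or("theta_cdf_lo", 0.05),
    theta_cdf_hi = get_or("theta_cdf_hi", 0.95),
    seed = get_or("seed", 1),
    name = get_or("name", basename(path)))
}

#' Write a network configuration to a YAML file
#'
#' @param config a [netlr_config()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "netlr_config"))
  W <- config$coupling$W
  p <- config$coupling$p_conn
  y <- c(list(name = config$name, N_E = config$N_E, N_I = config$N_I),
         unclass(config$intrinsic), unclass(config$synapses),
         list(W_EE = W["E", "E"], W_EI = W["E", "I"],
              W_IE = W["I", "E"], W_II = W["I", "I"],
              p_conn = list(EE = p["E", "E"], EI = p["E", "I"],
                            IE = p["I", "E"], II = p["I", "I"]),
              theta_cv = config$theta_cv,
              theta_cdf_lo = config$theta_cdf_lo,
              theta_cdf_hi = config$theta_cdf_hi,
              seed = config$seed))
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' @export
print.netlr_config <- function(x, ...) {
  W <- x$coupling$W
  cat("Network configuration:", x$name, "\n")
  cat(sprintf("  N_E = %d, N_I = %d (seed %d)\n", x$N_E, x$N_I, x$seed))
  cat(sprintf("  W_EE = %g, W_EI = %g, W_IE = %g, W_II = %g\n",
              W["E", "E"], W["E", "I"], W["I", "E"], W["I", "I"]))
  cat(sprintf("  sigma_E = %.4f, sigma_I = %.4f, theta_cv = %g\n",
              x$intrinsic$sigma_E, x$intrinsic$sigma_I, x$theta_cv))
  invisible(x)
}
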