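#' Specify a network-family sweep
#'
#' Cartesian grid over recurrent-excitation strengths `W_EE`, `W_IE` and
#' background-noise pairs `(sigma_E, sigma_I)`, all applied on top of a
#' base configuration. By default a single connectivity realization
#' (the base seed) is shared across all grid points so that differences
#' between rows reflect parameters, not graph resampling;
#' `resample = TRUE` draws a fresh graph per point (seed offset by the
#' row index).
#'
#' @param W_EE,W_IE numeric vectors of raw weights.
#' @param sigma_pairs matrix or data.frame with columns `sigma_E`,
#'   `sigma_I`; defaults to the base configuration's values.
#' @param base a [netlr_config()].
#' @param resample logical; fresh connectivity per grid point.
#' @return An object of class `"sweep_spec"`.
#' @export
sweep_spec <- function(W_EE, W_IE, sigma_pairs = NULL,
                       base = netlr_preset("asynchronous"),
                       resample = FALSE) {
  stopifnot(length(W_EE) >= 1, length(W_IE) >= 1, all(W_EE >= 0),
            all(W_IE >= 0), inherits(base, "netlr_config"))
  if (is.null(sigma_pairs))
    sigma_pairs <- data.frame(sigma_E = base$intrinsic$sigma_E,
                              sigma_I = base$intrinsic$sigma_I)
  sigma_pairs <- as.data.frame(sigma_pairs)
  stopifnot(all(c("sigma_E", "sigma_I") %in% names(sigma_pairs)))
  structure(list(W_EE = W_EE, W_IE = W_IE, sigma_pairs = sigma_pairs,
                 base = base, resample = resample),
            class = "sweep_spec")
}

#' Run a network-family sweep
#'
#' For every `(W_EE, W_IE, sigma pair)` grid point: rebuild the coupling,
#' solve the self-consistent rates, run the linear-response correlation
#' analysis with motif regressions over E-E pairs, and record the
#' population-averaged effective parameters. Failures are captured per
#' row (convergence flag and error string), never fatal to the sweep.
#'
#' @param spec a [sweep_spec()].
#' @param workers parallel workers via [parallel::mclapply()] (forked;
#'   1 = serial).
#' @param k_max motif-order cap for the regressions.
#' @param ... solver options forwarded to [solve_rates()]. Rows whose
#'   solve does not converge carry no statistics (all `NA`).
#' @return data.frame with one row per grid point: coordinates,
#'   `converged`, `error`, `spectral_radius`, population rates (Hz), mean
#'   E-E correlation, R-squared by motif order (`R2_order1` ...) and by
#'   second-order type (`R2_I_common` ...), and `mean_gI`, `E_rev`
#'   population averages.
#' @export
run_sweep <- function(spec, workers = 1, k_max = 4, ...) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- expand.grid(iW_EE = seq_along(spec$W_EE),
                      iW_IE = seq_along(spec$W_IE),
                      iSig = seq_len(nrow(spec$sigma_pairs)))
  one <- function(r) {
    g <- grid[r, ]
    cfg <- spec$base
    cfg$coupling$W["E", "E"] <- spec$W_EE[g$iW_EE]
    cfg$coupling$W["I", "E"] <- spec$W_IE[g$iW_IE]
    cfg$intrinsic$sigma_E <- spec$sigma_pairs$sigma_E[g$iSig]
    cfg$intrinsic$sigma_I <- spec$sigma_pairs$sigma_I[g$iSig]
    if (spec$resample) cfg$seed <- cfg$seed + r
    row <- data.frame(W_EE = spec$W_EE[g$iW_EE], W_IE = spec$W_IE[g$iW_IE],
                      sigma_E = cfg$intrinsic$sigma_E,
                      sigma_I = cfg$intrinsic$sigma_I,
                      seed = cfg$seed, converged = FALSE, error = "",
                      spectral_radius = NA_real_, rate_E_Hz = NA_real_,
                      rate_I_Hz = NA_real_, mean_rho_EE = NA_real_,
                      R2_order1 = NA_real_, R2_order2 = NA_real_,
                      R2_order3 = NA_real_, R2_order4 = NA_real_,
                      R2_E_common = NA_real_, R2_I_common = NA_real_,
                      R2_chain_corr = NA_real_, R2_chain_decorr = NA_real_,
                      mean_gI = NA_real_, E_rev = NA_real_,
                      SF_slope_whole = NA_real_, SF_slope_low = NA_real_,
                      stringsAsFactors = FALSE)
    out <- tryCatch({
      net <- suppressWarnings(build_network(cfg))
      fit <- suppressWarnings(solve_rates(net, ...))
      row$converged <- fit$converged
      if (!fit$converged) return(row)
      lr <- linear_response(fit, k_max = k_max)
      ps <- population_summary(fit)
      isE <- net$cell_type == "E"
      p <- lr$pairs
      ord <- motif_regression(p$rho,
                              setNames(lapply(1:k_max, function(k)
                                p[[paste0("R", k)]]),
                                paste0("order", 1:k_max)))
      typ <- motif_regression(p$R2, list(E_common = p$E_common,
                                         I_common = p$I_common,
                                         chain_corr = p$chain_correlating,
                                         chain_decorr = p$chain_decorrelating))
      row$spectral_radius <- lr$spectral_radius
      row$rate_E_Hz <- 1000 * mean(fit$rates[isE])
      row$rate_I_Hz <- 1000 * mean(fit$rates[!isE])
      row$mean_rho_EE <- mean(p$rho, na.rm = TRUE)
      row[paste0("R2_order", 1:4)] <- as.list(ord[1:4])
      row[c("R2_E_common", "R2_I_common", "R2_chain_corr",
            "R2_chain_decorr")] <- as.list(typ)
      row$mean_gI <- ps$mean_gI
      row$E_rev <- ps$E_rev
      curve <- sf_curve(fit)
      row$SF_slope_whole <- attr(curve, "slope_whole")
      row$SF_slope_low <- attr(curve, "slope_low_half")
      attr(row, "sf_curve") <- curve
      row
    }, error = function(e) { row$error <- conditionMessage(e); row })
    out
  }
  rows <- if (workers > 1)
    parallel::mclapply(seq_len(nrow(grid)), one, mc.cores = workers)
  else lapply(seq_len(nrow(grid)), one)
  out <- do.call(rbind, rows)
  attr(out, "sf_curves") <- lapply(rows, attr, "sf_curve")
  out
}
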