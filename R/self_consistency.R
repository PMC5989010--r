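#' Solve the self-consistent network firing rates
#'
#' Iterates the composition rates -> conductance moments -> effective
#' single-cell parameters -> threshold-integration rates with damping
#' `rate <- (1 - damping) * rate + damping * Phi(rate)` until the largest
#' per-cell rate change, relative to the largest rate in the network,
#' falls below `tol`. Initialization is at the uncoupled rates.
#'
#' @param network a `"netlr_network"`.
#' @param tol relative residual tolerance.
#' @param damping damping factor in (0, 1].
#' @param max_iter iteration cap; hitting it returns `converged = FALSE`
#'   (with a warning), never silently.
#' @param grid a [voltage_grid()] for the per-cell rate solves.
#' @return An object of class `"netlr_fit"`: per-cell `rates` (spikes/ms),
#'   effective parameters (`cells` data.frame), conductance `moments`,
#'   `iterations`, `residual`, `damping`, `converged`, and the network.
#' @export
solve_rates <- function(network, tol = 1e-6, damping = 0.5, max_iter = 500,
                        grid = voltage_grid()) {
  stopifnot(inherits(network, "netlr_network"),
            damping > 0, damping <= 1, tol > 0)
  intr <- network$intrinsic
  nu_max <- if (intr$tau_ref > 0) 1 / intr$tau_ref else Inf

  phi <- function(rates) {
    mom <- conductance_moments(network, rates)
    eff <- effective_parameters(network, mom)
    new <- vapply(seq_len(network$N), function(i)
      steady_rate(cell_from_row(network, eff, i), grid), numeric(1))
    list(rates = new, moments = mom, eff = eff)
  }

  rates <- phi(rep(0, network$N))$rates
  residual <- Inf
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- phi(rates)
    if (any(step$rates > nu_max)) {
      bad <- which(step$rates > nu_max)
      stop(sprintf("rate iteration unstable: cell(s) %s exceed 1/tau_ref",
                   paste(utils::head(bad, 5), collapse = ", ")))
    }
    residual <- max(abs(step$rates - rates)) / max(max(rates), 1e-12)
    rates <- (1 - damping) * rates + damping * step$rates
    if (residual < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("rate solver did not converge in %d iterations (residual %.3g)",
                    max_iter, residual))
  final <- phi(rates)
  structure(list(rates = rates, moments = final$moments, cells = final$eff,
                 iterations = iter, residual = residual, damping = damping,
                 tol = tol, converged = converged, grid = grid,
                 network = network),
            class = "netlr_fit")
}

#' @export
print.netlr_fit <- function(x, ...) {
  isE <- x$network$cell_type == "E"
  cat(sprintf("Self-consistent rate solution (%s after %d iterations, residual %.2g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual))
  cat(sprintf("  mean rate E: %.2f Hz, I: %.2f Hz\n",
              1000 * mean(x$rates[isE]), 1000 * mean(x$rates[!isE])))
  invisible(x)
}

#' @export
summary.netlr_fit <- function(object, ...) population_summary(object, ...)

#' @export
coef.netlr_fit <- function(object, ...) object$rates

#' Population-averaged effective parameters
#'
#' Arithmetic means of the per-cell effective parameters of a solved
#' network, by default over the excitatory population (the reference
#' values quoted for the presets are E-cell averages; the background-noise
#' entry `sigma_sqrt_taum` is the additive-noise amplitude
#' `sigma_E * sqrt(tau_m)` as it enters the effective voltage equation).
#'
#' @param fit a `"netlr_fit"` from [solve_rates()].
#' @param over `"E"` (default) or `"all"`.
#' @return A one-row data.frame with `mean_gE`, `mean_gI`, `sigma_gE`,
#'   `sigma_gI`, `sigma_sqrt_taum`, `E_rev`, `rate` (spikes/ms) and
#'   `rate_Hz`.
#' @export
population_summary <- function(fit, over = c("E", "all")) {
  stopifnot(inherits(fit, "netlr_fit"))
  over <- match.arg(over)
  keep <- if (over == "E") fit$network$cell_type == "E"
          else rep(TRUE, fit$network$N)
  m <- fit$moments[keep, ]
  cells <- fit$cells[keep, ]
  data.frame(
    over = over,
    mean_gE = mean(m$mean_gE), mean_gI = mean(m$mean_gI),
    sigma_gE = mean(sqrt(m$var_gE)), sigma_gI = mean(sqrt(m$var_gI)),
    sigma_sqrt_taum = mean(cells$sigma) * sqrt(fit$network$intrinsic$tau_m),
    E_rev = mean(cells$E_rev),
    rate = mean(fit$rates[keep]), rate_Hz = 1000 * mean(fit$rates[keep]))
}
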