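#' Reduced two-parameter firing-rate surface and correlation susceptibility
#'
#' Freezes all effective parameters except the mean inhibitory conductance
#' `g_I` and the threshold `theta` at supplied population averages and
#' evaluates the single-cell firing rate `F(g_I, theta)` on a grid by
#' threshold integration. The correlation susceptibility
#' \deqn{\hat S = (\partial F / \partial g_I)^2 / F}
#' (units Hz per squared dimensionless conductance) approximates how
#' strongly shared inhibitory input translates into pairwise spike-count
#' correlation for a cell at that operating point. Gradients use centered
#' differences (one-sided at the boundaries); `S_hat` is masked (`NA`)
#' where the rate vanishes.
#'
#' @param frozen one-row data.frame or named list with `mean_gE`,
#'   `sigma_gE`, `sigma_gI` (standard deviations) and `sigma` (background
#'   noise before the `sqrt(tau_m)` scaling), e.g. a [population_summary()]
#'   with `sigma = sigma_sqrt_taum / sqrt(tau_m)`.
#' @param gI_axis grid values of the mean inhibitory conductance; default
#'   spans 0.5 to 1.5 times `gI_center`.
#' @param theta_axis threshold grid; default spans the 1%-99% quantiles of
#'   the log-normal threshold distribution.
#' @param gI_center center of the default `gI_axis` (e.g. the solved
#'   population mean).
#' @param n_grid points per axis for the default axes.
#' @param intrinsic an [intrinsic_params()] for the remaining constants.
#' @param theta_cv log-normal scale for the default theta axis.
#' @param grid a [voltage_grid()].
#' @return An object of class `"netlr_surface"`: axes, `F_Hz`, `S_hat`,
#'   gradient arrays `dF` and `dS` (third dimension = d/dgI, d/dtheta),
#'   and the frozen-parameter record.
#' @export
rate_surface <- function(frozen, gI_axis = NULL, theta_axis = NULL,
                         gI_center = NULL, n_grid = 61,
                         intrinsic = intrinsic_params(), theta_cv = 0.2,
                         grid = voltage_grid()) {
  frozen <- as.list(frozen)
  needed <- c("mean_gE", "sigma_gE", "sigma_gI", "sigma")
  stopifnot(all(needed %in% names(frozen)))
  if (is.null(gI_axis)) {
    if (is.null(gI_center)) stop("supply gI_axis or gI_center")
    gI_axis <- seq(0.5 * gI_center, 1.5 * gI_center, length.out = n_grid)
  }
  if (is.null(theta_axis)) {
    qs <- qlnorm(c(0.01, 0.99), -theta_cv^2 / 2, theta_cv)
    theta_axis <- seq(qs[1], qs[2], length.out = n_grid)
  }
  stopifnot(all(diff(gI_axis) > 0), all(diff(theta_axis) > 0))

  F_Hz <- matrix(NA_real_, length(gI_axis), length(theta_axis))
  for (jt in seq_along(theta_axis)) {
    for (ig in seq_along(gI_axis)) {
      cell <- effective_cell(
        mean_gE = frozen$mean_gE, mean_gI = gI_axis[ig],
        sigma_gE2 = frozen$sigma_gE^2, sigma_gI2 = frozen$sigma_gI^2,
        sigma = frozen$sigma, theta = theta_axis[jt],
        tau_m = intrinsic$tau_m, tau_ref = intrinsic$tau_ref,
        v_reset = intrinsic$v_reset, E_E = intrinsic$E_E,
        E_I = intrinsic$E_I)
      F_Hz[ig, jt] <- 1000 * steady_rate(cell, grid)
    }
  }
  dF <- grad2d(F_Hz, gI_axis, theta_axis)
  S_hat <- dF[, , 1]^2 / F_Hz
  S_hat[F_Hz <= 0] <- NA_real_
  if (any(F_Hz <= 0))
    warning("rate vanishes on part of the grid; susceptibility masked there")
  dS <- grad2d(S_hat, gI_axis, theta_axis)
  structure(list(gI_axis = gI_axis, theta_axis = theta_axis, F_Hz = F_Hz,
                 S_hat = S_hat, dF = dF, dS = dS, frozen = frozen,
                 intrinsic = intrinsic),
            class = "netlr_surface")
}

# centered differences on a rectilinear grid, one-sided at boundaries;
# returns an array [i, j, 2] with d/dx1, d/dx2
grad2d <- function(M, x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  g <- array(NA_real_, c(n1, n2, 2))
  i_hi <- c(2:n1, n1); i_lo <- c(1, 1:(n1 - 1))
  g[, , 1] <- (M[i_hi, ] - M[i_lo, ]) / (x1[i_hi] - x1[i_lo])
  j_hi <- c(2:n2, n2); j_lo <- c(1, 1:(n2 - 1))
  g[, , 2] <- t((t(M)[j_hi, ] - t(M)[j_lo, ]) / (x2[j_hi] - x2[j_lo]))
  g
}

# bilinear interpolation of a grid matrix at (x1, x2) points
interp2 <- function(M, x1_axis, x2_axis, x1, x2) {
  i <- findInterval(x1, x1_axis, rightmost.closed = TRUE)
  j <- findInterval(x2, x2_axis, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1), length(x1_axis) - 1)
  j <- pmin(pmax(j, 1), length(x2_axis) - 1)
  tx <- (x1 - x1_axis[i]) / (x1_axis[i + 1] - x1_axis[i])
  ty <- (x2 - x2_axis[j]) / (x2_axis[j + 1] - x2_axis[j])
  M[cbind(i, j)] * (1 - tx) * (1 - ty) +
    M[cbind(i + 1, j)] * tx * (1 - ty) +
    M[cbind(i, j + 1)] * (1 - tx) * ty +
    M[cbind(i + 1, j + 1)] * tx * ty
}

#' Straight-line path through the surface
#'
#' Families follow the orientation of the `(theta, g_I)` plane as usually
#' plotted (threshold on the abscissa): a `"horizontal"` path varies the
#' threshold at fixed inhibitory conductance (the path a network whose
#' heterogeneity is purely threshold-based traverses), a `"vertical"`
#' path varies the inhibitory conductance at fixed threshold, and
#' `"radial"` paths pass through a common anchor at angle `angle`
#' (measured from the theta direction).
#'
#' @param family `"radial"`, `"horizontal"`, `"vertical"` or `"custom"`
#'   (explicit `anchor` + `direction`).
#' @param anchor point `c(gI, theta)`; for radial paths the common center
#'   (defaults to the grid midpoint).
#' @param angle direction angle in radians (radial/custom).
#' @param direction explicit direction vector `c(d_gI, d_theta)`
#'   (overrides `angle`).
#' @param n_points samples along the path.
#' @return An object of class `"path_spec"`.
#' @export
path_spec <- function(family = c("radial", "horizontal", "vertical",
                                 "custom"),
                      anchor = NULL, angle = 0, direction = NULL,
                      n_points = 101) {
  family <- match.arg(family)
  if (is.null(direction)) {
    # direction is (d_gI, d_theta); angle 0 points along theta
    direction <- switch(family,
      radial = c(sin(angle), cos(angle)),
      horizontal = c(0, 1),
      vertical = c(1, 0),
      custom = c(sin(angle), cos(angle)))
  }
  if (sqrt(sum(direction^2)) == 0) stop("path direction must be nonzero")
  structure(list(family = family, anchor = anchor,
                 direction = direction / sqrt(sum(direction^2)),
                 n_points = n_points),
            class = "path_spec")
}

#' Rate and susceptibility profile along a path
#'
#' Bilinear interpolation of `F` and `S_hat` (and their gradients) along a
#' straight-line path, plus the directional derivative
#' `dS/dF = (grad S . dx) / (grad F . dx)`, masked where the denominator
#' is negligible. Paths are truncated at the grid boundary.
#'
#' @param surface a `"netlr_surface"`.
#' @param path a [path_spec()].
#' @param denom_tol mask `dS/dF` where
#'   `|grad F . dx| < denom_tol * max |grad F . dx|`.
#' @return data.frame with `s` (arclength from the anchor), `gI`, `theta`,
#'   `F_Hz`, `S_hat`, `dFds`, `dSds`, `dSdF`.
#' @export
path_profile <- function(surface, path, denom_tol = 1e-12) {
  stopifnot(inherits(surface, "netlr_surface"), inherits(path, "path_spec"))
  gr <- range(surface$gI_axis); tr <- range(surface$theta_axis)
  anchor <- path$anchor
  if (is.null(anchor)) anchor <- c(mean(gr), mean(tr))
  d <- path$direction
  # arclength range keeping the path inside the grid
  lim <- function(a, lo, hi, dd) {
    if (dd == 0) {
      if (a < lo || a > hi) return(c(Inf, -Inf))
      return(c(-Inf, Inf))
    }
    sort(c((lo - a) / dd, (hi - a) / dd))
  }
  l1 <- lim(anchor[1], gr[1], gr[2], d[1])
  l2 <- lim(anchor[2], tr[1], tr[2], d[2])
  smin <- max(l1[1], l2[1]); smax <- min(l1[2], l2[2])
  if (!is.finite(smin) || !is.finite(smax) || smin >= smax)
    stop("path does not intersect the surface grid")
  s <- seq(smin, smax, length.out = path$n_points)
  gI <- anchor[1] + s * d[1]
  th <- anchor[2] + s * d[2]
  F_Hz <- interp2(surface$F_Hz, surface$gI_axis, surface$theta_axis, gI, th)
  S_hat <- interp2(surface$S_hat, surface$gI_axis, surface$theta_axis, gI, th)
  dFds <- interp2(surface$dF[, , 1], surface$gI_axis, surface$theta_axis,
                  gI, th) * d[1] +
          interp2(surface$dF[, , 2], surface$gI_axis, surface$theta_axis,
                  gI, th) * d[2]
  dSds <- interp2(surface$dS[, , 1], surface$gI_axis, surface$theta_axis,
                  gI, th) * d[1] +
          interp2(surface$dS[, , 2], surface$gI_axis, surface$theta_axis,
                  gI, th) * d[2]
  dSdF <- dSds / dFds
  dSdF[abs(dFds) < denom_tol * max(abs(dFds), na.rm = TRUE)] <- NA_real_
  data.frame(s = s, gI = gI, theta = th, F_Hz = F_Hz, S_hat = S_hat,
             dFds = dFds, dSds = dSds, dSdF = dSdF)
}

#' Gradient alignment of rate and susceptibility
#'
#' The angle between the gradients of `F` and `S_hat` at a point
#' determines the fraction of straight-line directions along which
#' susceptibility increases with firing rate:
#' `fraction = (pi - acos(cos_align)) / pi`.
#'
#' @param surface a `"netlr_surface"`.
#' @param point `c(gI, theta)`; defaults to the grid midpoint.
#' @return List with `point`, `grad_F`, `grad_S`, `cos_align` and
#'   `fraction_increasing`.
#' @export
alignment <- function(surface, point = NULL) {
  stopifnot(inherits(surface, "netlr_surface"))
  if (is.null(point))
    point <- c(mean(range(surface$gI_axis)),
               mean(range(surface$theta_axis)))
  gF <- c(interp2(surface$dF[, , 1], surface$gI_axis, surface$theta_axis,
                  point[1], point[2]),
          interp2(surface$dF[, , 2], surface$gI_axis, surface$theta_axis,
                  point[1], point[2]))
  gS <- c(interp2(surface$dS[, , 1], surface$gI_axis, surface$theta_axis,
                  point[1], point[2]),
          interp2(surface$dS[, , 2], surface$gI_axis, surface$theta_axis,
                  point[1], point[2]))
  nF <- sqrt(sum(gF^2)); nS <- sqrt(sum(gS^2))
  if (!is.finite(nF) || !is.finite(nS) || nF == 0 || nS == 0)
    stop("gradient undefined or zero at the requested point")
  ca <- sum(gF * gS) / (nF * nS)
  ca <- max(-1, min(1, ca))
  list(point = point, grad_F = gF, grad_S = gS, cos_align = ca,
       fraction_increasing = (pi - acos(ca)) / pi)
}

#' Sign map of the directional-derivative product
#'
#' For unit directions spanning the circle, the sign of
#' `(grad S . x)(grad F . x)`: positive where susceptibility and rate move
#' together along that direction. The fraction of positive directions
#' matches the closed-form alignment fraction.
#'
#' @param surface a `"netlr_surface"`.
#' @param point as in [alignment()].
#' @param n_directions number of directions.
#' @return data.frame with `angle`, `sign`, plus attribute
#'   `"fraction_positive"`.
#' @export
sign_map <- function(surface, point = NULL, n_directions = 360) {
  al <- alignment(surface, point)
  ang <- 2 * pi * (seq_len(n_directions) - 1) / n_directions
  dx1 <- cos(ang); dx2 <- sin(ang)
  pr <- (al$grad_S[1] * dx1 + al$grad_S[2] * dx2) *
        (al$grad_F[1] * dx1 + al$grad_F[2] * dx2)
  out <- data.frame(angle = ang, sign = sign(pr))
  attr(out, "fraction_positive") <- mean(pr > 0)
  out
}

#' Susceptibility-firing rate curve of a solved network
#'
#' The curve a threshold-heterogeneous network traces in the
#' `(F, S_hat)` plane: the reduced surface is evaluated with the solved
#' population-average parameters and traversed along the horizontal path
#' (threshold varying over the population's CDF range, inhibitory
#' conductance fixed at the solved mean). Returns the profile plus two
#' slope summaries: the OLS slope over the whole curve and over its
#' low-rate half.
#'
#' @param fit a `"netlr_fit"`.
#' @param n_grid surface resolution per axis.
#' @param theta_range threshold range of the curve; defaults to the
#'   population CDF range of the network configuration.
#' @return data.frame (`theta`, `F_Hz`, `S_hat`) with attributes
#'   `"slope_whole"` and `"slope_low_half"`.
#' @export
sf_curve <- function(fit, n_grid = 31, theta_range = NULL) {
  stopifnot(inherits(fit, "netlr_fit"))
  ps <- population_summary(fit)
  cfg <- fit$network$config
  frozen <- list(mean_gE = ps$mean_gE, sigma_gE = ps$sigma_gE,
                 sigma_gI = ps$sigma_gI,
                 sigma = ps$sigma_sqrt_taum /
                   sqrt(fit$network$intrinsic$tau_m))
  if (is.null(theta_range))
    theta_range <- qlnorm(c(cfg$theta_cdf_lo, cfg$theta_cdf_hi),
                          -cfg$theta_cv^2 / 2, cfg$theta_cv)
  surf <- rate_surface(frozen, gI_center = ps$mean_gI, n_grid = n_grid,
                       intrinsic = fit$network$intrinsic,
                       theta_cv = cfg$theta_cv)
  pp <- path_profile(surf, path_spec("horizontal",
                                     anchor = c(ps$mean_gI, 1),
                                     n_points = 2 * n_grid))
  pp <- pp[pp$theta >= theta_range[1] & pp$theta <= theta_range[2] &
             pp$F_Hz > 0, ]
  out <- pp[order(pp$F_Hz), c("theta", "F_Hz", "S_hat")]
  low <- out$F_Hz <= stats::median(out$F_Hz)
  attr(out, "slope_whole") <- unname(coef(lm(S_hat ~ F_Hz, out))[2])
  attr(out, "slope_low_half") <-
    unname(coef(lm(S_hat ~ F_Hz, out[low, ]))[2])
  out
}

#' Variance explained by single motif contributions
#'
#' Ordinary least-squares regression of the total pairwise correlation on
#' each candidate contribution separately, returning the coefficient of
#' determination per contribution.
#'
#' @param total numeric vector over pairs.
#' @param contributions named list of numeric vectors of the same length.
#' @param intercept include an intercept (default TRUE).
#' @return Named numeric vector of R-squared values; `NA` for constant
#'   regressors.
#' @export
motif_regression <- function(total, contributions, intercept = TRUE) {
  stopifnot(length(total) >= 3, is.list(contributions))
  vapply(contributions, function(x) {
    stopifnot(length(x) == length(total))
    keep <- is.finite(total) & is.finite(x)
    if (sd(x[keep]) == 0) return(NA_real_)
    f <- if (intercept) total[keep] ~ x[keep] else total[keep] ~ x[keep] - 1
    summary(lm(f))$r.squared
  }, numeric(1))
}

#' @export
print.netlr_surface <- function(x, ...) {
  cat(sprintf("Rate surface: %d x %d grid, gI in [%.3f, %.3f], theta in [%.3f, %.3f]\n",
              length(x$gI_axis), length(x$theta_axis),
              min(x$gI_axis), max(x$gI_axis),
              min(x$theta_axis), max(x$theta_axis)))
  cat(sprintf("  F range %.2f-%.2f Hz\n", min(x$F_Hz), max(x$F_Hz)))
  invisible(x)
}

#' @export
plot.netlr_surface <- function(x, what = c("F", "S"), ...) {
  what <- match.arg(what)
  M <- if (what == "F") x$F_Hz else x$S_hat
  graphics::image(x$gI_axis, x$theta_axis, M,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "mean inhibitory conductance",
                  ylab = "threshold",
                  main = if (what == "F") "firing rate (Hz)"
                         else "correlation susceptibility", ...)
  graphics::contour(x$gI_axis, x$theta_axis, M, add = TRUE,
                    col = "white", lwd = 0.5)
  invisible(x)
}
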