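#' Synaptic filter in the frequency domain
#'
#' Fourier transform (convention `f(omega) = int f(t) exp(-i omega t) dt`,
#' angular frequency in rad/ms) of the second-order alpha-synapse impulse
#' response with per-synapse amplitude `weight_hat`:
#' \deqn{\tilde J(\omega) = \hat\alpha \tau_r /
#'   [(1 + i\omega\tau_r)(1 + i\omega\tau_d)].}
#' The DC gain equals the mean-conductance factor `alpha_hat * tau_r`.
#'
#' @param omega angular frequencies (rad/ms).
#' @param tau_r,tau_d rise/decay time constants (ms).
#' @param weight_hat per-synapse pulse amplitude `alpha_hat`.
#' @return Complex vector.
#' @export
synaptic_filter <- function(omega, tau_r, tau_d, weight_hat = 1) {
  weight_hat * tau_r / ((1 + 1i * omega * tau_r) * (1 + 1i * omega * tau_d))
}

#' Variance-channel synaptic filter
#'
#' The filter mapping presynaptic rate modulations onto the conductance
#' *variance*; a frequency-independent rescaling of [synaptic_filter()]:
#' `L = J * (alpha_hat / 2) * tau_r / (tau_r + tau_d)`.
#'
#' @inheritParams synaptic_filter
#' @return Complex vector.
#' @export
variance_filter <- function(omega, tau_r, tau_d, weight_hat = 1) {
  synaptic_filter(omega, tau_r, tau_d, weight_hat) *
    (weight_hat / 2) * tau_r / (tau_r + tau_d)
}

#' Per-cell susceptibilities and uncoupled spectra on a frequency grid
#'
#' Runs the threshold-integration engine for every cell of a solved
#' network: the four susceptibility channels (mean/variance x E/I) and
#' the uncoupled power spectrum, at each requested frequency.
#'
#' @param fit a `"netlr_fit"` from [solve_rates()].
#' @param omega nonnegative angular frequencies (rad/ms).
#' @return List with `omega`, per-cell `rate`, `c0` (cells x frequencies
#'   matrix) and `A`, a list of four cells x frequencies complex matrices
#'   named by channel.
#' @export
susceptibility_set <- function(fit, omega = 0) {
  stopifnot(inherits(fit, "netlr_fit"))
  network <- fit$network
  grid <- fit$grid
  channels <- c("mean_gE", "mean_gI", "var_gE", "var_gI")
  nw <- length(omega)
  A <- lapply(channels, function(ch)
    matrix(complex(real = NA), network$N, nw))
  names(A) <- channels
  c0 <- matrix(NA_real_, network$N, nw)
  for (i in seq_len(network$N)) {
    cell <- cell_from_row(network, fit$cells, i)
    for (ch in channels)
      A[[ch]][i, ] <- susceptibility(cell, ch, omega, grid)
    c0[i, ] <- power_spectrum_uncoupled(cell, omega, grid)
  }
  list(omega = omega, rate = fit$rates, c0 = c0, A = A)
}

#' Interaction matrix of the linear-response network
#'
#' Entry (i, j) couples a rate modulation of source cell j into the rate
#' of target cell i through the mean- and variance-conductance channels of
#' the source's type X:
#' `K_ij = A_mean_gX,i * J_ij + A_var_gX,i * L_ij` on edges j -> i, zero
#' elsewhere. The per-synapse amplitude of the filters is the target's
#' `alpha_hat[i, X]`.
#'
#' @param network a `"netlr_network"`.
#' @param susc a [susceptibility_set()].
#' @param omega a single frequency present in `susc$omega`.
#' @return Complex N x N matrix (real at `omega = 0`), with attribute
#'   `"spectral_radius"`.
#' @export
interaction_matrix <- function(network, susc, omega = 0) {
  iw <- match(omega, susc$omega)
  if (is.na(iw)) stop("omega not present in the susceptibility set")
  syn <- network$synapses
  N <- network$N
  # per-target couplings for E and I source columns
  kE <- susc$A$mean_gE[, iw] *
    synaptic_filter(omega, syn$tau_r_E, syn$tau_d_E, network$alpha_hat[, "E"]) +
    susc$A$var_gE[, iw] *
    variance_filter(omega, syn$tau_r_E, syn$tau_d_E, network$alpha_hat[, "E"])
  kI <- susc$A$mean_gI[, iw] *
    synaptic_filter(omega, syn$tau_r_I, syn$tau_d_I, network$alpha_hat[, "I"]) +
    susc$A$var_gI[, iw] *
    variance_filter(omega, syn$tau_r_I, syn$tau_d_I, network$alpha_hat[, "I"])
  src_is_E <- network$cell_type == "E"
  K <- matrix(0 + 0i, N, N)
  K[, src_is_E] <- kE
  K[, !src_is_E] <- kI
  K <- K * network$adjacency
  if (omega == 0) K <- matrix(complex(real = Re(K)), N, N)
  attr(K, "spectral_radius") <- spectral_radius(K)
  K
}

#' Spectral radius
#'
#' Largest eigenvalue modulus; the linear-response motif series converges
#' when this is below one.
#'
#' @param K square matrix.
#' @return Nonnegative scalar.
#' @export
spectral_radius <- function(K) {
  max(Mod(eigen(unclass(K), only.values = TRUE)$values))
}

#' Network cross-spectrum at one frequency
#'
#' `C = (I - K)^{-1} C0 (I - K^H)^{-1}` with `C0` the diagonal matrix of
#' uncoupled spectra.
#'
#' @param C0 vector of uncoupled power-spectrum values (diagonal), or a
#'   full matrix.
#' @param K interaction matrix at the same frequency.
#' @return Complex (Hermitian) N x N matrix.
#' @export
cross_spectrum <- function(C0, K) {
  N <- nrow(K)
  C0m <- if (is.matrix(C0)) C0 else diag(C0, N)
  IK <- diag(N) - K
  radius <- spectral_radius(K)
  M <- tryCatch(solve(IK, C0m), error = function(e)
    stop(sprintf("I - K is singular (spectral radius %.4f)", radius)))
  M %*% solve(Conj(t(IK)))
}

#' Long-time Pearson correlation matrix
#'
#' Normalizes the zero-frequency cross-spectrum: the long-window limit of
#' the spike-count correlation coefficient is
#' `C_ij(0) / sqrt(C_ii(0) C_jj(0))`. Pairs involving a zero-variance
#' cell are `NA` (undefined, not zero).
#'
#' @param C cross-spectrum matrix at zero frequency (real).
#' @return Correlation matrix with unit diagonal.
#' @export
long_time_correlation <- function(C) {
  C <- Re(C)
  d <- diag(C)
  if (any(d < 0)) stop("negative spectral variance")
  s <- sqrt(d)
  rho <- C / outer(s, s)
  rho[, d == 0] <- NA_real_
  rho[d == 0, ] <- NA_real_
  diag(rho)[d > 0] <- 1
  rho
}

#' Motif-order contribution to the normalized correlation
#'
#' Order-k term of the motif expansion of the cross-spectrum,
#' \deqn{R^k = \sum_{l=0}^{k} K^l C^0 (K^H)^{k-l},}
#' normalized by `sqrt(C_ii C_jj)` of the full cross-spectrum (the order-0
#' term is the normalized uncoupled spectrum). Order k collects all
#' directed paths with k edges: chains and common inputs.
#'
#' @param C0 vector (diagonal) or matrix of uncoupled spectra.
#' @param K interaction matrix.
#' @param k motif order (>= 0).
#' @param norm optional vector of `C_ii` values of the full cross-spectrum
#'   used for normalization; computed from `C0` and `K` when `NULL`.
#' @return N x N matrix (real part at zero frequency).
#' @export
motif_term <- function(C0, K, k, norm = NULL) {
  stopifnot(k >= 0)
  N <- nrow(K)
  C0m <- if (is.matrix(C0)) C0 else diag(C0, N)
  if (is.null(norm)) norm <- Re(diag(cross_spectrum(C0, K)))
  KH <- Conj(t(K))
  acc <- matrix(0 + 0i, N, N)
  left <- diag(1 + 0i, N)           # K^l
  rights <- vector("list", k + 1)   # (K^H)^(k-l)
  rights[[k + 1]] <- diag(1 + 0i, N)
  if (k >= 1) for (l in k:1) rights[[l]] <- rights[[l + 1]] %*% KH
  for (l in 0:k) {
    acc <- acc + left %*% C0m %*% rights[[l + 1]]
    if (l < k) left <- left %*% K
  }
  s <- sqrt(norm)
  out <- acc / outer(s, s)
  if (all(Im(out) == 0)) Re(out) else out
}

#' Second-order motif-type decomposition
#'
#' Splits the order-2 motif term into four parts: common input from
#' excitatory sources, common input from inhibitory sources (the
#' `K C0 K^H` term split by source type), and chain contributions
#' (`K^2 C0 + C0 (K^H)^2`) split into correlating and decorrelating
#' classes by the sign of each individual two-edge path's contribution.
#' The four matrices sum to [motif_term()] at k = 2.
#'
#' @param C0 vector (diagonal) of uncoupled spectra.
#' @param K real interaction matrix at zero frequency.
#' @param network the `"netlr_network"` (for source types).
#' @param norm as in [motif_term()].
#' @return List of four N x N matrices: `E_common`, `I_common`,
#'   `chain_correlating`, `chain_decorrelating`.
#' @export
second_order_split <- function(C0, K, network, norm = NULL) {
  K <- Re(unclass(K))
  N <- nrow(K)
  c0 <- if (is.matrix(C0)) diag(C0) else C0
  if (is.null(norm)) norm <- Re(diag(cross_spectrum(c0, K)))
  s <- sqrt(norm)
  nrm <- outer(s, s)
  isE <- network$cell_type == "E"

  common_part <- function(keep) {
    Kk <- K[, keep, drop = FALSE]
    (Kk %*% (c0[keep] * t(Kk))) / nrm
  }
  Kp <- pmax(K, 0); Km <- pmax(-K, 0)
  # two-edge chains j -> l -> i contribute K_il K_lj C0_jj to C_ij; the
  # transposed term collects chains into j. Same-sign edge products are
  # correlating, opposite-sign products decorrelating.
  pos_chain <- Kp %*% Kp + Km %*% Km
  neg_chain <- Kp %*% Km + Km %*% Kp
  chain_pos <- sweep(pos_chain, 2, c0, `*`)
  chain_neg <- -sweep(neg_chain, 2, c0, `*`)
  chain_corr <- (chain_pos + t(chain_pos)) / nrm
  chain_decorr <- (chain_neg + t(chain_neg)) / nrm
  list(E_common = common_part(isE), I_common = common_part(!isE),
       chain_correlating = chain_corr, chain_decorrelating = chain_decorr)
}

#' Linear-response correlation analysis of a solved network
#'
#' Assembles the zero-frequency interaction matrix from the solved
#' susceptibilities and synaptic filters, computes the network
#' cross-spectrum, the long-time Pearson correlation matrix, the
#' motif-order terms up to `k_max`, and the second-order motif-type
#' decomposition.
#'
#' @param fit a `"netlr_fit"` from [solve_rates()].
#' @param k_max highest motif order retained.
#' @return An object of class `"netlr_correlation"`: `K` (real matrix),
#'   `spectral_radius`, `C0` (vector), `C` (matrix), `rho`, `R` (list of
#'   motif terms, `R[[k + 1]]` = order k), `split` (four matrices),
#'   `pairs` (data.frame over unordered E-E pairs with the total
#'   correlation, motif terms and split columns).
#' @export
linear_response <- function(fit, k_max = 4) {
  stopifnot(inherits(fit, "netlr_fit"))
  network <- fit$network
  susc <- susceptibility_set(fit, omega = 0)
  K <- Re(interaction_matrix(network, susc, omega = 0))
  c0 <- susc$c0[, 1]
  C <- Re(cross_spectrum(c0, K))
  norm <- diag(C)
  rho <- long_time_correlation(C)
  R <- lapply(0:k_max, function(k) Re(motif_term(c0, K, k, norm = norm)))
  names(R) <- paste0("order", 0:k_max)
  split <- second_order_split(c0, K, network, norm = norm)

  isE <- which(network$cell_type == "E")
  pr <- t(utils::combn(isE, 2))
  idx <- cbind(pr[, 1], pr[, 2])
  pairs <- data.frame(i = pr[, 1], j = pr[, 2], rho = rho[idx])
  for (k in 1:k_max) pairs[[paste0("R", k)]] <- R[[k + 1]][idx]
  pairs$E_common <- split$E_common[idx]
  pairs$I_common <- split$I_common[idx]
  pairs$chain_correlating <- split$chain_correlating[idx]
  pairs$chain_decorrelating <- split$chain_decorrelating[idx]

  structure(list(K = K, spectral_radius = spectral_radius(K), C0 = c0,
                 C = C, rho = rho, R = R, split = split, pairs = pairs,
                 k_max = k_max, rates = fit$rates, network = network),
            class = "netlr_correlation")
}

#' @export
print.netlr_correlation <- function(x, ...) {
  cat(sprintf("Linear-response correlation analysis (N = %d)\n",
              nrow(x$K)))
  cat(sprintf("  spectral radius of K(0): %.4f\n", x$spectral_radius))
  cat(sprintf("  mean E-E correlation: %.4f over %d pairs\n",
              mean(x$pairs$rho, na.rm = TRUE), nrow(x$pairs)))
  invisible(x)
}
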