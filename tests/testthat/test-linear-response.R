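test_that("synaptic filter matches the integrated impulse response", {
  # numerically integrate the two-stage synapse against a unit impulse
  tau_r <- 1; tau_d <- 5; a_hat <- 0.7
  dt <- 1e-3
  tt <- seq(0, 80, by = dt)
  g <- g1 <- numeric(length(tt))
  g1[1] <- a_hat
  for (k in seq_along(tt)[-1]) {
    g[k] <- g[k - 1] + dt * (-g[k - 1] + g1[k - 1]) / tau_d
    g1[k] <- g1[k - 1] - dt * g1[k - 1] / tau_r
  }
  analytic <- a_hat * tau_r / (tau_r - tau_d) *
    (exp(-tt / tau_r) - exp(-tt / tau_d))
  expect_lt(max(abs(g - analytic)), 1e-3 * max(analytic))
  # DC gain equals the integral of the impulse response and the
  # mean-conductance factor alpha_hat * tau_r
  expect_equal(Re(synaptic_filter(0, tau_r, tau_d, a_hat)),
               sum(analytic) * dt, tolerance = 1e-3)
  expect_equal(synaptic_filter(0, tau_r, tau_d, a_hat), a_hat * tau_r + 0i)
  # low-pass: magnitude strictly decreasing
  om <- seq(0, 10, length.out = 50)
  expect_true(all(diff(Mod(synaptic_filter(om, tau_r, tau_d, a_hat))) < 0))
})

test_that("variance filter is a frequency-independent rescaling", {
  om <- c(0, 0.3, 2, 9)
  r <- variance_filter(om, 1, 5, 1) / synaptic_filter(om, 1, 5, 1)
  expect_equal(r, rep(1 / 12 + 0i, 4))
  expect_true(all(variance_filter(om, 2, 10, 0) == 0))
})

test_that("interaction matrix entries carry the two-channel coupling", {
  net <- make_fixture("uncoupled_pair")
  fit <- solve_rates(net)
  susc <- susceptibility_set(fit, 0)
  expect_true(all(interaction_matrix(net, susc, 0) == 0))
  expect_error(interaction_matrix(net, susc, 0.123), "omega")

  chain <- make_fixture("two_by_two_analytic")
  fitc <- solve_rates(chain)
  sc <- susceptibility_set(fitc, 0)
  K <- Re(interaction_matrix(chain, sc, 0))
  expect_equal(which(K != 0), 2L)  # only source 1 -> target 2
  # dual route: finite differences of the stationary rate through both
  # channels, combined with the filter DC gains
  syn <- chain$synapses
  ah <- chain$alpha_hat[2, "E"]
  m <- fitc$moments[2, ]
  eff <- fitc$cells
  g <- tgrid
  f <- function(dgE, dvE) steady_rate(effective_cell(
    mean_gE = m$mean_gE + dgE, mean_gI = m$mean_gI,
    sigma_gE2 = m$var_gE + dvE, sigma_gI2 = m$var_gI,
    sigma = eff$sigma[2], theta = eff$theta[2]), g)
  dm <- (f(1e-4, 0) - f(-1e-4, 0)) / 2e-4
  dv <- (f(0, 1e-6) - f(0, -1e-6)) / 2e-6
  hand <- unname(dm * ah * syn$tau_r_E +
    dv * ah^2 * syn$tau_r_E^2 / (2 * (syn$tau_r_E + syn$tau_d_E)))
  expect_equal(K[2, 1], hand, tolerance = 0.01)
})

test_that("inhibitory columns of K are negative at zero frequency", {
  fit <- solve_rates(make_fixture("mini_asyn"))
  susc <- susceptibility_set(fit, 0)
  K <- Re(interaction_matrix(fit$network, susc, 0))
  isI <- fit$network$cell_type == "I"
  offdiag <- K[, isI][K[, isI] != 0]
  expect_true(all(offdiag < 0))
  expect_true(all(K[!fit$network$adjacency] == 0))
})

test_that("cross-spectrum reduces correctly and inverts a 2x2 analytically", {
  c0 <- c(0.011, 0.007)
  K0 <- matrix(0, 2, 2)
  expect_equal(cross_spectrum(c0, K0), diag(c0))
  k <- 0.37
  K <- matrix(c(0, k, 0, 0), 2, 2)  # edge 1 -> 2
  C <- cross_spectrum(c0, K)
  # (I-K)^{-1} = [[1,0],[k,1]]: closed form
  expect_equal(C, matrix(c(c0[1], k * c0[1],
                           k * c0[1], k^2 * c0[1] + c0[2]), 2, 2),
               tolerance = 1e-14)
  # singular I - K is reported with the spectral radius
  expect_error(cross_spectrum(c0, diag(2)), "singular")
})

test_that("motif series partial sums converge to the direct inverse", {
  set.seed(1)
  N <- 6
  K0 <- matrix(rnorm(N * N, 0, 0.3), N, N)
  c0 <- runif(N, 0.005, 0.02)
  err_at <- function(K, kmax) {
    C <- cross_spectrum(c0, K)
    norm <- diag(C)
    partial <- Reduce(`+`, lapply(0:kmax, motif_term, C0 = c0, K = K,
                                  norm = norm))
    max(abs(partial - C / sqrt(outer(norm, norm))))
  }
  # convergent regime: truncation error gone at moderate order
  expect_lt(err_at(K0 * 0.45 / spectral_radius(K0), 20), 1e-6)
  # geometric convergence: error shrinks by ~ rho(K) per order
  K5 <- K0 * 0.5 / spectral_radius(K0)
  expect_lt(err_at(K5, 14) / err_at(K5, 10), 0.6^4)
})

test_that("motif terms decompose by order", {
  set.seed(2)
  N <- 5
  K <- matrix(rnorm(N * N, 0, 0.2), N, N)
  c0 <- runif(N, 0.005, 0.02)
  norm <- rep(1, N)
  expect_true(all(motif_term(c0, K * 0, 3, norm = norm) == 0))
  # k = 2 term enumerates l = 0, 1, 2 exactly
  C0m <- diag(c0)
  expect_equal(motif_term(c0, K, 2, norm = norm),
               K %*% C0m %*% t(K) + K %*% K %*% C0m + C0m %*% t(K) %*% t(K),
               tolerance = 1e-14)
})

test_that("long-time correlation normalizes the zero-frequency spectrum", {
  C <- diag(c(2, 3, 4))
  expect_equal(long_time_correlation(C), diag(3))
  C2 <- matrix(c(2, sqrt(6), sqrt(6), 3), 2, 2)
  expect_equal(long_time_correlation(C2)[1, 2], 1)
  C3 <- diag(c(1, 0))
  rho <- long_time_correlation(C3)
  expect_true(is.na(rho[1, 2]))
})

test_that("second-order split partitions the order-2 term", {
  fit <- solve_rates(make_fixture("mini_asyn"))
  lr <- linear_response(fit)
  total2 <- lr$split$E_common + lr$split$I_common +
    lr$split$chain_correlating + lr$split$chain_decorrelating
  expect_equal(total2, lr$R$order2, tolerance = 1e-12)
  expect_true(all(lr$split$chain_correlating >= 0))
  expect_true(all(lr$split$chain_decorrelating <= 0))
})

test_that("a pure common-inhibition motif follows the single-source formula", {
  net <- make_fixture("common_I_source")
  fit <- solve_rates(net)
  lr <- linear_response(fit)
  # only inhibitory common input: no E common term, no chains
  expect_true(all(lr$split$E_common == 0))
  expect_true(all(lr$split$chain_correlating == 0))
  expect_true(all(lr$split$chain_decorrelating == 0))
  # the pair correlation is positive: product of two negative couplings
  expect_gt(lr$rho[2, 3], 0)
  # hand evaluation from the solved susceptibilities and filters
  susc <- susceptibility_set(fit, 0)
  syn <- net$synapses
  k2 <- Re(susc$A$mean_gI[2, 1]) *
    Re(synaptic_filter(0, syn$tau_r_I, syn$tau_d_I, net$alpha_hat[2, "I"])) +
    Re(susc$A$var_gI[2, 1]) *
    Re(variance_filter(0, syn$tau_r_I, syn$tau_d_I, net$alpha_hat[2, "I"]))
  k3 <- Re(susc$A$mean_gI[3, 1]) *
    Re(synaptic_filter(0, syn$tau_r_I, syn$tau_d_I, net$alpha_hat[3, "I"])) +
    Re(susc$A$var_gI[3, 1]) *
    Re(variance_filter(0, syn$tau_r_I, syn$tau_d_I, net$alpha_hat[3, "I"]))
  hand <- unname(k2 * lr$C0[1] * k3 / sqrt(lr$C[2, 2] * lr$C[3, 3]))
  expect_equal(lr$split$I_common[2, 3], hand, tolerance = 1e-10)
  expect_lt(k2, 0)
  expect_lt(k3, 0)
})

test_that("the cross-spectrum is Hermitian positive semidefinite off zero", {
  fit <- solve_rates(make_fixture("mini_asyn"))
  susc <- susceptibility_set(fit, omega = c(0, 0.5, 2))
  for (w in c(0.5, 2)) {
    K <- interaction_matrix(fit$network, susc, w)
    C <- cross_spectrum(susc$c0[, match(w, susc$omega)], K)
    expect_lt(max(Mod(C - Conj(t(C)))), 1e-12)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10 * sum(Re(diag(C))))
  }
})
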