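test_that("threshold quantiles are deterministic log-normal with mean 1", {
  th <- sample_thresholds(19, 0.2, 0.05, 0.95)
  expect_length(th, 19)
  expect_true(all(diff(th) > 0))
  # underlying normal location is forced to -cv^2/2 by the unit mean
  p <- 0.05 + 0.9 * (0:18) / 18
  expect_equal(th, qlnorm(p, -0.02, 0.2))
  # identical across calls (no RNG involved)
  expect_identical(th, sample_thresholds(19, 0.2, 0.05, 0.95))
  # distribution moments: dense quantile average approximates mean 1 and
  # variance exp(cv^2) - 1
  pp <- seq(5e-5, 1 - 5e-5, length.out = 20001)
  q <- qlnorm(pp, -0.02, 0.2)
  expect_equal(mean(q), 1, tolerance = 1e-3)
  expect_equal(var(q), exp(0.04) - 1, tolerance = 2e-2)
  # single threshold = median; zero heterogeneity = all ones
  expect_equal(sample_thresholds(1, 0.2), exp(-0.02))
  expect_equal(sample_thresholds(5, 0), rep(1, 5))
  expect_error(sample_thresholds(3, 0.2, 0, 0.95), "CDF")
  expect_error(sample_thresholds(3, 0.2, 0.5, 1), "CDF")
})

test_that("network construction realizes Bernoulli connectivity", {
  cfg <- netlr_preset("asynchronous", seed = 7)
  net <- build_network(cfg)
  expect_s3_class(net, "netlr_network")
  expect_equal(net$N, 100)
  expect_true(all(diag(net$adjacency) == 0))
  expect_true(all(net$theta > net$intrinsic$v_reset))
  # realized in-degrees equal row sums of the adjacency
  isE <- net$cell_type == "E"
  expect_equal(net$in_degree[, "E"],
               rowSums(net$adjacency[, isE]))
  # binomial expectation: E cells receive on average ~ 0.35 * 20 I inputs
  expect_equal(mean(net$in_degree[isE, "I"]), 0.35 * 20, tolerance = 0.12)
  expect_equal(mean(net$in_degree[isE, "E"]), 0.40 * 80, tolerance = 0.05)
  # reproducible under the same seed, different under another
  net2 <- build_network(cfg)
  expect_identical(net$adjacency, net2$adjacency)
  net3 <- build_network(cfg, seed = 8)
  expect_false(identical(net$adjacency, net3$adjacency))
  # reference weights as configured
  W <- net$coupling$W
  expect_equal(unname(c(W["E", "I"], W["I", "E"], W["E", "E"], W["I", "I"])),
               c(10, 5, 0.5, 5))
})

test_that("empty connectivity gives empty adjacency and zero in-degree", {
  cfg <- netlr_config(N_E = 5, N_I = 2,
                      coupling = coupling_spec(p_EE = 0, p_EI = 0,
                                               p_IE = 0, p_II = 0))
  net <- suppressWarnings(build_network(cfg))
  expect_true(all(net$adjacency == 0))
  expect_true(all(net$in_degree == 0))
  expect_true(all(net$alpha_hat == 0))
  # zero in-degree with nonzero weight is flagged (once per source type)
  expect_warning(expect_warning(build_network(cfg), "zero"), "zero")
})

test_that("conductance moments follow the Poisson-drive formulas", {
  net <- make_fixture("mini_asyn")
  expect_error(conductance_moments(net, rep(-1, net$N)), "nonnegative")
  m0 <- conductance_moments(net, rep(0, net$N))
  expect_true(all(m0[, c("mean_gE", "var_gE", "mean_gI", "var_gI")] == 0))
  # var/mean ratio is (alpha_hat/2) tau_r/(tau_r+tau_d) for any rates
  rates <- seq(0.005, 0.05, length.out = net$N)
  m <- conductance_moments(net, rates)
  syn <- net$synapses
  expect_equal(m$var_gI / m$mean_gI,
               net$alpha_hat[, "I"] / 2 * syn$tau_r_I /
                 (syn$tau_r_I + syn$tau_d_I))
  expect_equal(m$var_gE / m$mean_gE,
               net$alpha_hat[, "E"] / 2 * syn$tau_r_E /
                 (syn$tau_r_E + syn$tau_d_E))
})

test_that("stationary synapse moments match a Monte Carlo Poisson drive", {
  # single synapse, alpha_hat = 1, nu = 0.01/ms, E kinetics
  mc <- poisson_synapse_moments(0.01, 1, 1, 5, duration = 3e5, seed = 2)
  expect_equal(mc$mean, 0.01, tolerance = 0.05)
  expect_equal(mc$var, 0.5 * 0.01 * (1 / 6), tolerance = 0.05)
})

test_that("effective parameters implement the conductance lumping", {
  net <- make_fixture("uncoupled_pair")
  m0 <- conductance_moments(net, c(0, 0))
  eff <- effective_parameters(net, m0)
  expect_equal(eff$g0, c(1, 1))
  expect_equal(eff$E_rev, c(0, 0))
  # reference operating point: <g_E> = 0.0053, <g_I> = 1.83
  cell <- effective_cell(mean_gE = 0.0053, mean_gI = 1.83)
  expect_equal(cell$g0, 2.8353)
  expect_equal(cell$E_rev, (0.0053 * 6.5 - 1.83 * 0.5) / 2.8353,
               tolerance = 1e-12)
  expect_equal(round(cell$E_rev, 4), -0.3106)
  # E_rev approaches E_E as excitation dominates
  big <- effective_cell(mean_gE = 1e6, mean_gI = 1.83)
  expect_equal(big$E_rev, 6.5, tolerance = 1e-5)
})

test_that("mean conductance is in-degree invariant; variance scales as 1/N_in", {
  # uniform presynaptic rate: alpha_hat * N_in * nu * tau_r = alpha W nu tau_r
  cfg <- netlr_config(N_E = 40, N_I = 10,
                      coupling = coupling_spec(p_EE = 0.3, p_EI = 0.8,
                                               p_IE = 0.3, p_II = 0.8))
  net <- suppressWarnings(build_network(cfg, seed = 3))
  nu <- 0.02
  m <- conductance_moments(net, rep(nu, net$N))
  syn <- net$synapses
  W <- net$coupling$W
  isE <- net$cell_type == "E"
  okI <- net$in_degree[, "I"] > 0
  expect_equal(m$mean_gI[isE & okI],
               rep(syn$alpha_I * W["E", "I"] * nu * syn$tau_r_I,
                   sum(isE & okI)))
  # variance * N_in is constant across cells of the same type
  vN <- (m$var_gI * net$in_degree[, "I"])[isE & okI]
  expect_lt(diff(range(vN)) / mean(vN), 1e-12)
})

test_that("configs round-trip through YAML", {
  cfg <- netlr_preset("strong_asynchronous", seed = 4)
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  cfg2$name <- cfg$name
  expect_equal(cfg2$coupling$W, cfg$coupling$W)
  expect_equal(cfg2$intrinsic$sigma_E, cfg$intrinsic$sigma_E)
  expect_equal(cfg2$seed, 4L)
  unlink(path)
})
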