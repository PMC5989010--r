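test_that("vanishing noise recovers the deterministic oscillator period", {
  # suprathreshold drift: period tau_m/g0 * log(Erev/(Erev - theta)) + tref
  cell <- effective_cell(g0 = 2, E_rev = 2, sigma = 1e-3, theta = 1,
                         tau_m = 20, tau_ref = 2)
  expect_equal(steady_rate(cell), 1 / (10 * log(2) + 2), tolerance = 1e-3)
  # subthreshold, vanishing noise: silent
  sub <- effective_cell(g0 = 2, E_rev = 0.5, sigma = 0.05, theta = 1)
  expect_lt(steady_rate(sub), 1e-10)
})

test_that("additive-noise rates match the Siegert quadrature", {
  for (pars in list(c(2.8, -0.31, 0.9), c(1.6, 0.1, 1.4),
                    c(2.2, -0.2, 2.0))) {
    cell <- effective_cell(g0 = pars[1], E_rev = pars[2], sigma = pars[3],
                           theta = 1)
    expect_equal(steady_rate(cell, voltage_grid(2048)), siegert_rate(cell),
                 tolerance = 0.005)
  }
})

test_that("rate is monotone decreasing in threshold and stable under refinement", {
  base <- random_cells(1)[[1]]
  rates <- vapply(seq(0.8, 1.4, by = 0.1), function(th) {
    cl <- base; cl$theta <- th
    steady_rate(cl)
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
  r1 <- steady_rate(base, voltage_grid(1024))
  r2 <- steady_rate(base, voltage_grid(2048))
  expect_lt(abs(r1 - r2) / r2, 1e-3)
  # dual route: normalization rate equals inverse mean first passage
  expect_equal(steady_rate(base), isi_moments(base)$rate, tolerance = 2e-3)
})

test_that("zero-frequency susceptibility equals the rate derivative", {
  cells <- random_cells(10)
  for (cell in cells) {
    fd <- rate_derivatives(cell)
    for (ch in names(fd)) {
      a0 <- Re(susceptibility(cell, ch, 0, tgrid))
      expect_equal(a0, unname(fd[ch]), tolerance = 0.01)
    }
    # susceptibility signs: excitation up, inhibition down
    expect_gt(fd["mean_gE"], 0)
    expect_lt(fd["mean_gI"], 0)
  }
})

test_that("susceptibility magnitude behaves at frequency extremes", {
  cell <- effective_cell(mean_gE = 0.0053, mean_gI = 1.83,
                         sigma_gE2 = 6.9e-6, sigma_gI2 = 0.436,
                         sigma = 2 / sqrt(2), theta = 1)
  om <- c(0, 1e-3, 10)
  for (ch in c("mean_gE", "mean_gI")) {
    A <- susceptibility(cell, ch, om, tgrid)
    # continuity of the omega -> 0 limit
    expect_equal(Re(A[2]), Re(A[1]), tolerance = 0.01)
    # high-frequency rolloff of the mean-conductance response
    expect_lt(Mod(A[3]), 0.25 * Mod(A[1]))
  }
  # a silent cell has nothing to modulate
  dead <- effective_cell(g0 = 2, E_rev = 0.2, sigma = 0.08, theta = 1.3)
  expect_true(all(Mod(susceptibility(dead, "mean_gE", c(0, 1))) < 1e-8))
  expect_true(all(power_spectrum_uncoupled(dead, c(0, 1)) < 1e-12))
  expect_error(susceptibility(cell, "conductance"), "arg")
})

test_that("uncoupled power spectrum has renewal structure", {
  cell <- effective_cell(mean_gE = 0.0053, mean_gI = 1.83,
                         sigma_gE2 = 6.9e-6, sigma_gI2 = 0.436,
                         sigma = 2 / sqrt(2), theta = 1)
  nu <- steady_rate(cell, tgrid)
  sp <- power_spectrum_uncoupled(cell, c(0, 3, 10), tgrid)
  expect_true(all(sp >= 0))
  # high-frequency limit is the rate
  expect_equal(sp[3], nu, tolerance = 0.01)
  # zero-frequency value is rate * CV^2 of the ISI
  mom <- isi_moments(cell, tgrid)
  expect_equal(sp[1], nu * mom$cv2, tolerance = 1e-6)
  # a high-noise low-rate cell is close to Poisson: flat spectrum ~ rate
  pois <- effective_cell(g0 = 1.5, E_rev = -0.2, sigma = 1.2, theta = 1.4)
  nup <- steady_rate(pois, tgrid)
  spp <- power_spectrum_uncoupled(pois, c(0, 0.05, 0.5, 2), tgrid)
  expect_true(all(abs(spp / nup - 1) < 0.15))
})

test_that("spectrum and rate agree with a long effective-cell simulation", {
  cell <- effective_cell(mean_gE = 0.0053, mean_gI = 1.83,
                         sigma_gE2 = 6.9e-6, sigma_gI2 = 0.436,
                         sigma = 2 / sqrt(2), theta = 1)
  dur <- 3e6
  sim <- simulate_cell(cell, duration = dur, dt = 0.004, seed = 4)
  tms <- sim$times[sim$times > 1000] - 1000
  span <- dur - 1000
  nu_mc <- length(tms) / span
  nu_ti <- steady_rate(cell, tgrid)
  expect_equal(nu_mc, nu_ti, tolerance = 0.02)
  # binned periodogram vs the threshold-integration spectrum, shape
  # normalized by the respective rates
  db <- 2
  nb <- floor(span / db)
  y <- tabulate(pmin(floor(tms / db) + 1, nb), nbins = nb) / db
  psd <- db * Mod(fft(y - mean(y)))^2 / nb
  fre <- 2 * pi * (seq_len(nb) - 1) / (nb * db)
  for (w in c(0.05, 0.2, 0.8)) {
    band <- fre > 0.9 * w & fre < 1.1 * w
    expect_equal(mean(psd[band]) / nu_mc,
                 power_spectrum_uncoupled(cell, w, tgrid) / nu_ti,
                 tolerance = 0.1)
  }
  # long-window count variance estimates the zero-frequency spectrum
  cs <- count_statistics(sim, T_win = 500, from = 1000)
  expect_equal((cs$var / cs$T_win) / nu_mc,
               power_spectrum_uncoupled(cell, 0, tgrid) / nu_ti,
               tolerance = 0.1)
})

test_that("monte carlo rates confirm threshold integration on a cell panel", {
  cells <- random_cells(5)
  for (i in seq_along(cells)) {
    ti <- steady_rate(cells[[i]])
    s <- simulate_cell(cells[[i]], duration = 3e5, dt = 0.01, seed = i)
    mc <- sum(s$times > 500) / (3e5 - 500)
    expect_equal(mc, ti, tolerance = 0.03)
  }
})

test_that("diagnostic density integrates to the non-refractory fraction", {
  cell <- random_cells(1)[[1]]
  out <- steady_rate(cell, density = TRUE)
  dv <- diff(out$v[1:2])
  mass <- sum(out$density) * dv
  expect_equal(mass + out$rate * cell$tau_ref, 1, tolerance = 1e-3)
  expect_true(all(out$density >= 0))
})
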