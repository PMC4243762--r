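test_that("compute_gp matches closed forms and rejects bad input", {
  expect_equal(compute_gp(5, 5), 0)
  expect_equal(compute_gp(1, 0), 1)
  expect_equal(compute_gp(0, 1), -1)
  expect_equal(compute_gp(3, 1), 0.5)
  expect_error(compute_gp(0, 0), "undefined")
  expect_error(compute_gp(-1, 2), "non-negative")
})

test_that("GP is bounded and antisymmetric under channel swap", {
  set.seed(11)
  a <- runif(200, 0, 10)
  b <- runif(200, 0, 10)
  gp <- compute_gp(a, b)
  expect_true(all(gp >= -1 & gp <= 1))
  expect_equal(compute_gp(b, a), -gp)
})

test_that("gp_from_spectrum handles point reads and band integration", {
  flat <- emission_spectrum(370:600, rep(2, 231))
  expect_equal(gp_from_spectrum(flat), 0)
  expect_equal(gp_from_spectrum(flat, bandwidth = 10), 0)

  # narrow band at 440, nothing at 490
  wl <- 370:600
  y <- exp(-((wl - 440) / 3)^2)
  blue <- emission_spectrum(wl, y)
  expect_equal(gp_from_spectrum(blue), 1, tolerance = 1e-12)

  # two-band spectrum: hand-computed point reads at on-grid centers
  sp <- two_band_spectrum(w_ict = 0.3)
  i440 <- 0.7 + 0.3 * exp(-4 / 2)  # exact band values at the grid points
  i490 <- 0.7 * exp(-4 / 2) + 0.3
  expect_equal(gp_from_spectrum(sp), (i440 - i490) / (i440 + i490),
               tolerance = 1e-12)
  expect_error(gp_from_spectrum(sp, centers = c(300, 490)), "range")
})

test_that("relative quantum yield follows the comparative formula", {
  ref <- qy_sample(area = 200, od = 0.04, n = 1.4266)
  expect_equal(quantum_yield(ref, ref, phi_ref = 0.97), 0.97)

  doubled <- qy_sample(area = 400, od = 0.04, n = 1.4266)
  expect_equal(quantum_yield(doubled, ref, phi_ref = 0.5), 1.0)

  s <- qy_sample(area = 100, od = 0.02, n = 1.45)
  r <- qy_sample(area = 200, od = 0.04, n = 1.43)
  expect_equal(quantum_yield(s, r, phi_ref = 0.97),
               0.97 * (100 / 200) * (0.04 / 0.02) * (1.45 / 1.43)^2)
})

test_that("quantum yield scales linearly in area and inversely in OD", {
  ref <- qy_sample(200, 0.04, 1.43)
  base <- quantum_yield(qy_sample(100, 0.02, 1.45), ref, 0.5)
  expect_equal(quantum_yield(qy_sample(300, 0.02, 1.45), ref, 0.5), 3 * base)
  expect_equal(quantum_yield(qy_sample(100, 0.04, 1.45), ref, 0.5), base / 2)
  expect_warning(qy_sample(100, 0.2, 1.4), "inner-filter")
})

test_that("rate constants reproduce tabulated values and sum to 1/tau", {
  k <- rate_constants(0.61, 2.78)  # laurdan in chloroform
  expect_equal(round_half_up(k$kr, 2), 0.22)
  expect_equal(round_half_up(k$knr, 2), 0.14)
  k <- rate_constants(0.16, 1.26)  # C-laurdan in methanol
  expect_equal(round_half_up(k$kr, 2), 0.13)
  expect_equal(round_half_up(k$knr, 2), 0.67)
  expect_equal(rate_constants(1, 2), list(kr = 0.5, knr = 0))

  set.seed(7)
  phi <- runif(50)
  tau <- runif(50, 0.1, 10)
  k <- rate_constants(phi, tau)
  expect_equal(k$kr + k$knr, 1 / tau, tolerance = 1e-15)
  expect_error(rate_constants(0.5, 0), "> 0")
})

test_that("brightness reproduces the reported values at nearest-100 rounding", {
  tab <- probe_table()
  expect_equal(brightness(tab$epsilon_360, tab$phi), tab$brightness)
  expect_equal(brightness(12345, 0), 0)
  expect_equal(brightness(12345, 0.5, round_to = 0), 6172.5)
})

test_that("GP-relaxation correlation recovers exact and noisy lines", {
  th <- 1:6
  expect_equal(gp_relaxation_correlation(th, 0.1 + 0.05 * th)$pearson_r, 1)
  expect_equal(gp_relaxation_correlation(th, 0.9 - 0.05 * th)$pearson_r, -1)

  set.seed(42)
  theta <- runif(12, 1, 8)
  gp <- 0.05 + 0.08 * theta + rnorm(12, sd = 0.03)
  f <- gp_relaxation_correlation(theta, gp)
  expect_lt(abs(f$slope - 0.08), 3 * f$slope_se)

  expect_error(gp_relaxation_correlation(1:2, 1:2), "insufficient")
  expect_error(gp_relaxation_correlation(rep(2, 5), 1:5), "insufficient")
})

test_that("probe and spectrum constructors enforce their invariants", {
  expect_error(probe_record("x", epsilon_360 = -1, phi = 0.5), "> 0")
  expect_error(probe_record("x", epsilon_360 = 1000, phi = 1.2), "\\[0, 1\\]")
  expect_error(emission_spectrum(c(400, 390), c(1, 1)), "ascending")
  expect_error(emission_spectrum(c(390, 400), c(1, -1)), "non-negative")
})
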