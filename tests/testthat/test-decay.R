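test_that("decay model matches closed forms", {
  single <- decay_components(1, 2)
  expect_equal(decay_model(single, 0), 1)
  expect_equal(decay_model(single, 2), exp(-1))
  duo <- decay_components(c(0.6, 0.4), c(5.8, 0.5))
  expect_equal(decay_model(duo, 1), 0.6 * exp(-1 / 5.8) + 0.4 * exp(-1 / 0.5))
  expect_error(decay_model(single, -1), "non-negative")
  expect_error(decay_components(c(0.5, 0.4), c(1, 2)), "sum to 1")
  expect_error(decay_components(numeric(0), numeric(0)), "empty")
})

test_that("mean lifetime reproduces tabulated rows and stays bounded", {
  expect_equal(round_half_up(mean_lifetime(
    decay_components(c(0.56, 0.44), c(6.18, 0.53))), 2), 5.82)
  expect_equal(round_half_up(mean_lifetime(
    decay_components(c(0.64, 0.36), c(3.42, 0.64))), 2), 3.16)
  expect_equal(mean_lifetime(decay_components(1, 4.35)), 4.35)

  set.seed(3)
  for (i in 1:50) {
    a <- runif(2)
    tau <- runif(2, 0.1, 10)
    mt <- mean_lifetime(decay_components(a / sum(a), tau))
    expect_gte(mt, min(tau))
    expect_lte(mt, max(tau))
  }
})

test_that("simulated decays are seeded, Poisson-scaled and IRF-aware", {
  duo <- decay_components(c(0.6, 0.4), c(5, 0.8))
  h1 <- simulate_decay(duo, total_counts = 1e5, seed = 9)
  h2 <- simulate_decay(duo, total_counts = 1e5, seed = 9)
  expect_identical(h1$counts, h2$counts)

  # delta IRF leaves the expectation unchanged
  delta <- c(1, rep(0, 1023))
  e0 <- simulate_decay(duo, total_counts = 1e6, poisson = FALSE)
  e1 <- simulate_decay(duo, irf = delta, total_counts = 1e6, poisson = FALSE)
  expect_equal(e1$counts, e0$counts, tolerance = 1e-12)

  # noiseless single-exponential log-counts slope = -1/tau
  e <- simulate_decay(decay_components(1, 2), total_counts = 1e6,
                      poisson = FALSE)
  sl <- coef(lm(log(e$counts) ~ e$bin_centers))[2]
  expect_equal(unname(sl), -0.5, tolerance = 0.01)

  expect_error(simulate_decay(duo, irf = c(1, 0, 0), total_counts = 10),
               "length")
})

test_that("noiseless decays are fitted exactly and scale-invariantly", {
  e <- simulate_decay(decay_components(1, 3), total_counts = 1e6,
                      poisson = FALSE)
  f <- fit_decay(e, 1)
  expect_equal(f$components$tau, 3, tolerance = 1e-6)
  expect_lt(f$chi2, 1e-10)

  e10 <- decay_histogram(e$bin_centers, e$counts * 10)
  f10 <- fit_decay(e10, 1)
  expect_equal(f10$components$tau, f$components$tau, tolerance = 1e-6)

  expect_error(fit_decay(e, 3), "unsupported")
})

test_that("simulate-fit round trip recovers two-component parameters", {
  truth <- decay_components(c(0.56, 0.44), c(6.18, 0.53))
  irf <- gaussian_irf()
  errs <- t(sapply(1:5, function(s) {
    f <- fit_decay(simulate_decay(truth, irf = irf, total_counts = 1e6,
                                  seed = 100 + s), 2)
    c(abs(f$components$tau / truth$tau - 1),
      abs(f$components$alpha - truth$alpha))
  }))
  expect_lte(median(errs[, 1]), 0.05)
  expect_lte(median(errs[, 2]), 0.05)
  expect_lte(median(errs[, 3]), 0.05)
})

test_that("model selection separates one- from two-component decays", {
  h1 <- simulate_decay(decay_components(1, 3), total_counts = 1e6, seed = 1)
  expect_equal(select_model(h1)$n_components, 1L)

  h2 <- simulate_decay(decay_components(c(0.5, 0.5), c(5, 0.8)),
                       total_counts = 1e6, seed = 2)
  expect_equal(select_model(h2)$n_components, 2L)
  expect_equal(select_model(h2, chi2_improvement_threshold = Inf)$n_components,
               1L)
})

test_that("decay histogram constructor validates its contract", {
  expect_error(decay_histogram(c(1, 2, 4), c(1, 1, 1)), "uniform")
  expect_error(decay_histogram(1:5, c(1, -1, 1, 1, 1)), "non-negative")
  expect_error(decay_histogram(1:5, rep(1, 5), irf = 1:3), "same number")
})
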