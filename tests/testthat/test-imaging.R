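make_stack <- function(i440, i490, centers = c(440, 490)) {
  spectral_stack(array(c(i440, i490), dim = c(dim(i440), 2)), centers)
}

test_that("uniform equal-channel stacks give an all-zero fully unmasked map", {
  m <- matrix(50, 8, 8)
  gm <- gp_map(make_stack(m, m))
  expect_true(all(gm$mask))
  expect_true(all(gm$gp == 0))
})

test_that("gp_map equals the scalar GP pixelwise on unmasked pixels", {
  set.seed(31)
  ia <- matrix(rpois(400, 200), 20, 20)
  ib <- matrix(rpois(400, 150), 20, 20)
  gm <- gp_map(make_stack(ia, ib), min_total_intensity = 50)
  idx <- which(gm$mask)
  expect_equal(gm$gp[idx], compute_gp(ia[idx], ib[idx]))
  expect_true(all(is.na(gm$gp[!gm$mask])))
  expect_true(all(gm$gp[idx] >= -1 & gm$gp[idx] <= 1))
})

test_that("gp_map is invariant under exposure scaling and masks monotonically", {
  set.seed(32)
  ia <- matrix(runif(100, 10, 100), 10, 10)
  ib <- matrix(runif(100, 10, 100), 10, 10)
  g1 <- gp_map(make_stack(ia, ib))
  g2 <- gp_map(make_stack(4 * ia, 4 * ib))
  expect_equal(g2$gp, g1$gp, tolerance = 1e-12)

  m_lo <- gp_map(make_stack(ia, ib), min_total_intensity = 40)$mask
  m_hi <- gp_map(make_stack(ia, ib), min_total_intensity = 120)$mask
  expect_true(all(m_lo >= m_hi))  # raising the threshold never unmasks
})

test_that("dark images are fully masked and missing channels rejected", {
  dark <- matrix(0, 5, 5)
  gm <- gp_map(make_stack(dark, dark), min_total_intensity = 1)
  expect_false(any(gm$mask))
  expect_error(gp_histogram(gm), "empty map")
  expect_error(gp_map(make_stack(dark, dark, centers = c(430, 490))),
               "no channel within 1 nm")
})

test_that("two-region scenes recover the construction GPs", {
  reg <- two_region_labels()
  stack <- gen_scene(reg, region_gp = c(0.4, -0.2),
                     region_intensity = c(1e4, 1e4), seed = 41)
  gm <- gp_map(stack, min_total_intensity = 100)
  expect_equal(mean(gm$gp[reg == 1 & gm$mask]), 0.4, tolerance = 0.02)
  expect_equal(mean(gm$gp[reg == 2 & gm$mask]), -0.2, tolerance = 0.02)
})

test_that("total fluorescence sums the selected channels", {
  a <- matrix(1:12, 3, 4)
  one <- spectral_stack(array(a, dim = c(3, 4, 1)), 500)
  expect_equal(total_fluorescence(one), a)

  two <- make_stack(a, a)
  expect_equal(total_fluorescence(two), 2 * a)
  expect_equal(total_fluorescence(two, band = c(480, 500)), a)
  expect_error(total_fluorescence(two, band = c(600, 700)), "empty band")

  reg <- two_region_labels(10, 10)
  stack <- gen_scene(reg, c(0.1, 0.3), c(100, 200), poisson = FALSE,
                     channel_centers = c(440, 490))
  expect_equal(total_fluorescence(stack),
               matrix(c(rep(100, 50), rep(200, 50)), 10, 10),
               tolerance = 1e-9)
})

test_that("gp_histogram summarizes the unmasked distribution", {
  m <- matrix(50, 6, 6)
  h <- gp_histogram(gp_map(make_stack(m, m)))
  expect_equal(h$mean, 0)
  expect_equal(sum(h$counts > 0), 1)

  reg <- two_region_labels()
  stack <- gen_scene(reg, c(0.4, -0.2), c(1e4, 1e4), seed = 43)
  gm <- gp_map(stack, min_total_intensity = 100)
  h <- gp_histogram(gm, bins = 40)
  occupied <- h$mids[h$counts > 0.2 * max(h$counts)]
  expect_true(any(abs(occupied - 0.4) < 0.05))
  expect_true(any(abs(occupied - (-0.2)) < 0.05))

  # masking out one region leaves a unimodal distribution at the other GP
  gm2 <- gm
  gm2$mask[reg == 2] <- FALSE
  gm2$gp[reg == 2] <- NA
  h2 <- gp_histogram(gm2, bins = 40)
  expect_lt(abs(h2$mode - 0.4), 0.06)
})
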