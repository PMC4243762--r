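test_that("spectrum generator spans the LE/ICT limits", {
  model <- spectrum_model(noise_sd = 0)
  chcl3 <- lookup_solvent("chloroform")
  expect_gt(gp_from_spectrum(gen_spectrum(model, chcl3, w = 0)), 0)
  expect_lt(gp_from_spectrum(gen_spectrum(model, chcl3, w = 1)), 0)

  # calibration brackets: nonpolar high GP, protic eps > 20 negative GP
  expect_gt(gp_from_spectrum(gen_spectrum(model, chcl3)), 0.4)
  expect_lt(gp_from_spectrum(gen_spectrum(model, lookup_solvent("ethanol"))),
            -0.2)
  expect_lt(gp_from_spectrum(gen_spectrum(model, lookup_solvent("methanol"))),
            -0.2)
})

test_that("ICT weight grows with dielectric constant and protic character", {
  model <- spectrum_model()
  eps <- seq(2, 60, length.out = 20)
  w <- sapply(eps, function(e)
    ict_weight(model, solvent_spec("m", e, class = "polar-aprotic")))
  expect_true(all(diff(w) > 0))
  expect_gt(ict_weight(model, solvent_spec("p", 25, class = "polar-protic")),
            ict_weight(model, solvent_spec("a", 25, class = "polar-aprotic")))
})

test_that("every generator is bit-reproducible under a fixed seed", {
  model <- spectrum_model()
  sv <- lookup_solvent("acetone")
  expect_identical(gen_spectrum(model, sv, seed = 5)$intensities,
                   gen_spectrum(model, sv, seed = 5)$intensities)
  expect_identical(gen_thermal_scan(seed = 5)$values,
                   gen_thermal_scan(seed = 5)$values)
  expect_identical(gen_insertion_trace(seed = 5)$intensities,
                   gen_insertion_trace(seed = 5)$intensities)
  expect_identical(
    unlist(gen_polarized(0.2, 1e5, poisson = TRUE, seed = 5)),
    unlist(gen_polarized(0.2, 1e5, poisson = TRUE, seed = 5)))
  reg <- two_region_labels(8, 8)
  expect_identical(gen_scene(reg, c(0.1, 0.2), c(100, 100), seed = 5)$pixels,
                   gen_scene(reg, c(0.1, 0.2), c(100, 100), seed = 5)$pixels)
})

test_that("generator outputs satisfy their container invariants", {
  sp <- gen_spectrum(spectrum_model(), lookup_solvent("water"), seed = 1)
  expect_s3_class(sp, "emission_spectrum")
  expect_true(all(sp$intensities >= 0))
  expect_true(all(diff(sp$wavelengths) > 0))

  sc <- gen_thermal_scan(seed = 1)
  expect_s3_class(sc, "thermal_scan")
  expect_length(sc$temperatures, 26)

  tr <- gen_insertion_trace(seed = 1)
  expect_s3_class(tr, "kinetic_trace")
  expect_true(all(tr$intensities >= 0))
})

test_that("Poisson-noised polarized intensities recover r to counting error", {
  errs <- sapply(1:20, function(s) {
    p <- gen_polarized(0.25, 1e6, g_true = 0.95, poisson = TRUE, seed = s)
    steady_state_anisotropy(p) - 0.25
  })
  expect_true(all(abs(errs) < 0.005))
})

test_that("insertion traces show the expected saturation shape", {
  tr <- gen_insertion_trace(imax = 100, t_half = 5, noise_sd = 0)
  expect_equal(tr$intensities[tr$times == 5], 50)
  expect_gte(tr$intensities[tr$times == 60], 80)  # duration >= 4 * t_half

  # slow inserter: still visibly rising at 40 min
  slow <- gen_insertion_trace(imax = 100, t_half = 12, noise_sd = 0)
  i40 <- slow$intensities[slow$times == 40]
  i60 <- slow$intensities[slow$times == 60]
  expect_lt(i40, 0.8 * 100)
  expect_gt(i60 - i40, 2)
})

test_that("single-region and dark-background scenes behave as constructed", {
  reg <- matrix(1L, 12, 12)
  gm <- gp_map(gen_scene(reg, 0, 1e4, seed = 6), min_total_intensity = 10)
  expect_lt(abs(mean(gm$gp[gm$mask])), 0.02)

  reg[, 1:4] <- 0L  # dark background
  stack <- gen_scene(reg, 0.3, 1e3, seed = 7)
  gm <- gp_map(stack, min_total_intensity = 1)
  expect_false(any(gm$mask[, 1:4]))
  expect_true(all(gm$mask[, 5:12]))
})
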