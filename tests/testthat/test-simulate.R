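test_that("detector resolution follows square-root scaling from the Mn anchor", {
  d <- detector_model()
  expect_equal(fwhm_at(5.895, d), 0.135)
  expect_equal(fwhm_at(4 * 5.895, d), 0.270)
  expect_equal(fwhm_at(10.52, d), 0.135 * sqrt(10.52 / 5.895), tolerance = 1e-12)
  expect_error(fwhm_at(0, d), class = "xrfnet_domain_error")
})

test_that("expected spectra are linear in concentration over a zero continuum", {
  m0 <- matrix_profile(0, 0, continuum_amplitude = 0, background_cv = 0)
  z <- expected_spectrum(0, 0, m0)
  expect_true(all(z$total_counts == 0) && all(z$background_counts == 0))

  s1 <- expected_spectrum(100, 0, m0)
  s2 <- expected_spectrum(200, 0, m0)
  net1 <- s1$total_counts - s1$background_counts
  net2 <- s2$total_counts - s2$background_counts
  expect_equal(net2, 2 * net1, tolerance = 1e-12)

  # slope recovery within 1% on a noiseless ladder
  ladder <- c(50, 150, 300, 450, 600)
  areas <- vapply(ladder, function(conc) {
    s <- expected_spectrum(conc, 0, m0)
    sum(s$total_counts - s$background_counts)
  }, numeric(1))
  fit <- stats::lm(areas ~ ladder)
  d <- detector_model()
  lines <- emission_lines()
  expected_slope <- d$sensitivity *
    sum(lines$shell_yield[lines$element == "As"] * lines$branch[lines$element == "As"])
  expect_equal(unname(stats::coef(fit)[2]), expected_slope, tolerance = 0.01)
})

test_that("fluorescence-yield and branching ratios match the line physics", {
  m0 <- matrix_profile(0, 0, continuum_amplitude = 0, background_cv = 0)
  principal <- emission_lines()[emission_lines()$label %in% c("Ka", "La"), ]
  as_area <- sum(expected_spectrum(100, 0, m0, lines = principal)$total_counts)
  pb_area <- sum(expected_spectrum(0, 100, m0, lines = principal)$total_counts)
  expect_equal(as_area / pb_area, 0.549 / 0.386, tolerance = 1e-6)

  pb_only <- expected_spectrum(100, 0, m0) # no Pb -> As lines only
  pb_spec <- expected_spectrum(0, 100, m0)
  la <- sum(pb_spec$total_counts[pb_spec$energy_keV < 11.5])
  lb <- sum(pb_spec$total_counts[pb_spec$energy_keV >= 11.9])
  expect_equal(la / lb, 1.61, tolerance = 1e-6)
})

test_that("the As Ka / Pb La overlap is unresolvable at detector resolution", {
  d <- detector_model()
  expect_gt(fwhm_at(10.5, d), 0.15) # far above the 0.02 keV separation
  m0 <- matrix_profile(0, 0, continuum_amplitude = 0, background_cv = 0)
  mix <- expected_spectrum(100, 100 * 0.549 / 0.386, m0) # equal-weight mixture
  peak_e <- mix$energy_keV[which.max(mix$total_counts)]
  expect_gte(peak_e, 10.50)
  expect_lte(peak_e, 10.52)
})

test_that("Poisson sampling is deterministic given the seed and mean-faithful", {
  ex <- expected_spectrum(150, 100)
  expect_identical(sample_spectrum(ex, 42), sample_spectrum(ex, 42))
  expect_false(identical(sample_spectrum(ex, 42), sample_spectrum(ex, 43)))
  expect_true(all(sample_spectrum(ex, 1)$background_counts == ex$background_counts))

  # a zero-mean channel stays zero; the replicate mean tracks the expectation
  m0 <- matrix_profile(0, 0, continuum_amplitude = 0, background_cv = 0)
  z <- expected_spectrum(0, 0, m0)
  expect_true(all(sample_spectrum(z, 7)$total_counts == 0))

  ch <- which.min(abs(ex$energy_keV - 10.52))
  draws <- vapply(1:2000, function(i) {
    sample_spectrum(ex[ch, ], seed = 10000 + i)$total_counts
  }, numeric(1))
  mu <- ex$total_counts[ch]
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(mu / 2000))
})

test_that("calibration-set generation combines spikes with intrinsic levels", {
  design <- default_calibration_design()
  sim <- simulate_standards(design, seed = 4)
  expect_equal(nrow(sim$standards), 28)
  expect_equal(nrow(sim$spectra), 28 * 9 * 321) # 252 acquisitions
  # a zero-spike standard on Unit 2 records the intrinsic contamination
  zero <- sim$standards[design$spiked_as == 0 & design$spiked_pb == 0 &
                          design$matrix_unit == "unit2", ][1, ]
  expect_equal(zero$as_ug_kg, 87.82)
  expect_equal(zero$pb_ug_kg, 3.19)

  expect_identical(simulate_standards(design[1:2, ], seed = 4),
                   simulate_standards(design[1:2, ], seed = 4))
  bad <- design[1, ]; bad$matrix_unit <- "granite"
  expect_error(simulate_standards(bad, seed = 1), class = "xrfnet_config_error")
  expect_error(simulate_standards(design[0, ], seed = 1),
               class = "xrfnet_config_error")
})

test_that("scenario sets hold the documented As/Pb totals and size", {
  s1 <- simulate_scenario(1, seed = 6)
  expect_equal(nrow(s1$standards), 10)
  expect_true(all(s1$standards$as_ug_kg == 128.97))
  expect_true(all(s1$standards$pb_ug_kg == calrose_unit2()$intrinsic_pb))
  expect_equal(length(unique(paste(s1$spectra$standard_id, s1$spectra$pellet_id,
                                   s1$spectra$repeat_id))), 90)

  s2 <- simulate_scenario(2, seed = 6)
  expect_true(all(s2$standards$as_ug_kg == 128.97))
  expect_true(all(s2$standards$pb_ug_kg == 208.95))
  expect_error(simulate_scenario(3, seed = 1), class = "xrfnet_config_error")
})

test_that("validation design mirrors the reference sample panel", {
  vd <- validation_design()
  expect_equal(nrow(vd), 1 + 11 + 12)
  expect_equal(sort(unique(vd$category)), c("commercial", "crm", "pb_spiked"))
  expect_equal(vd$as_ug_kg[vd$category == "crm"], 263.63)
  expect_equal(range(vd$as_ug_kg[vd$category == "commercial"]), c(56.84, 296.72))

  sim <- simulate_validation(seed = 8)
  expect_equal(nrow(sim$standards), 24)
  expect_equal(sim$samples$standard_id, sprintf("val%02d", 1:24))
})
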