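test_that("CSV parsing infers the grid and round-trips simulated spectra exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "standard_id,pellet_id,repeat_id,energy_keV,total_counts,background_counts,live_time_s",
    "a,1,1,10.35,100,40,120",
    "a,1,1,10.36,50,50,120",
    "a,1,1,10.37,80,45,120"
  ), path)
  s <- read_spectra(path)
  expect_equal(nrow(s), 3)
  g <- xrfnet:::infer_grid(s$energy_keV)
  expect_equal(g$step_keV, 0.01)
  expect_equal(g$n_channels, 3L)

  # round trip of simulator output
  sim <- tiny_calibration(n = 2, seed = 3)
  out <- withr::local_tempfile(fileext = ".csv")
  write_spectra(sim$spectra, out)
  back <- read_spectra(out)
  expect_equal(as.data.frame(back), as.data.frame(sim$spectra[, names(back)]))
})

test_that("malformed spectra files are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "standard_id,pellet_id,repeat_id,energy_keV,total_counts,live_time_s",
    "a,1,1,10.35,100,120"
  ), path)
  expect_error(read_spectra(path), class = "xrfnet_format_error")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "standard_id,pellet_id,repeat_id,energy_keV,total_counts,background_counts,live_time_s",
    "a,1,1,10.35,-5,40,120"
  ), path2)
  expect_error(read_spectra(path2), class = "xrfnet_validation_error")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "standard_id,pellet_id,repeat_id,energy_keV,total_counts,background_counts,live_time_s",
    "a,1,1,10.35,5,4,120",
    "a,1,1,10.36,5,4,120",
    "a,1,1,10.40,5,4,120"
  ), path3)
  expect_error(read_spectra(path3), class = "xrfnet_grid_error")
})

test_that("background subtraction is channelwise and never clamped", {
  s <- tibble::tibble(
    standard_id = "a", pellet_id = 1L, repeat_id = 1L,
    energy_keV = c(10.35, 10.36), live_time_s = 120,
    total_counts = c(100, 50), background_counts = c(40, 50)
  )
  expect_equal(subtract_background(s)$net_counts, c(60, 0))

  s$total_counts <- s$background_counts
  expect_equal(subtract_background(s)$net_counts, c(0, 0))

  s$total_counts <- c(10, 5); s$background_counts <- c(12, 5)
  expect_equal(subtract_background(s)$net_counts, c(-2, 0))
})

test_that("window extraction selects closed-interval channels and is linear", {
  det <- detector_model() # 10.00-13.20 keV, 0.01 keV channels
  spec <- expected_spectrum(100, 50, detector = det)
  f <- extract_features(spec, region_spec())
  expect_length(f, 36 + 46)

  expect_error(extract_features(spec, region_spec(list(c(10.355, 10.356)))),
               class = "xrfnet_empty_window_error")

  full <- region_spec(list(c(det$grid_lo_keV - 1e-6, det$grid_hi_keV + 1e-6)))
  net <- subtract_background(spec)$net_counts
  expect_equal(unname(extract_features(spec, full)), net)

  # linearity on a fixed grid
  s1 <- expected_spectrum(120, 10, detector = det)
  s2 <- expected_spectrum(30, 300, detector = det)
  mix <- s1
  mix$total_counts <- 2 * s1$total_counts + 3 * s2$total_counts
  mix$background_counts <- 2 * s1$background_counts + 3 * s2$background_counts
  expect_equal(extract_features(mix, region_spec()),
               2 * extract_features(s1, region_spec()) +
                 3 * extract_features(s2, region_spec()))
})

test_that("dataset assembly yields one row per spectrum with replicated targets", {
  sim <- simulate_standards(default_calibration_design(), seed = 2)
  ft <- assemble_dataset(sim$spectra, sim$standards)
  expect_equal(nrow(ft), 28 * 9) # 252 spectra
  expect_equal(sum(grepl("^ch_", names(ft))), 82)
  # targets constant within a standard
  per <- dplyr::distinct(ft, standard_id, as_ug_kg, pb_ug_kg)
  expect_equal(nrow(per), 28)

  four <- unique(sim$standards$standard_id)[1:4]
  ft4 <- assemble_dataset(
    dplyr::filter(sim$spectra, standard_id %in% four),
    dplyr::filter(sim$standards, standard_id %in% four)
  )
  expect_equal(nrow(ft4), 36) # 4 standards x 9 spectra

  one <- sim$spectra %>%
    dplyr::filter(standard_id == four[1], pellet_id == 1, repeat_id == 1)
  ft1 <- assemble_dataset(one, sim$standards)
  expect_equal(nrow(ft1), 1)
  expect_equal(ft1$as_ug_kg, sim$standards$as_ug_kg[1])

  # permuting the standards permutes rows, content unchanged
  perm <- sim$spectra %>% dplyr::arrange(dplyr::desc(standard_id))
  ftp <- assemble_dataset(perm, sim$standards)
  expect_equal(
    as.data.frame(dplyr::arrange(ftp, standard_id, pellet_id, repeat_id)),
    as.data.frame(dplyr::arrange(ft, standard_id, pellet_id, repeat_id))
  )
})

test_that("mixed energy grids are rejected at assembly", {
  sim <- tiny_calibration(n = 2, seed = 9)
  shifted <- sim$spectra
  idx <- shifted$standard_id == shifted$standard_id[1]
  shifted$energy_keV[idx] <- shifted$energy_keV[idx] + 0.001
  expect_error(assemble_dataset(shifted, sim$standards),
               class = "xrfnet_grid_error")
})

test_that("replicate summaries use the sample (n-1) convention", {
  expect_equal(summarize_replicates(c(1, 1, 1)), c(mean = 1, sd = 0))
  s <- summarize_replicates(c(rep(0, 9), 10))
  expect_equal(s[["mean"]], 1)
  expect_equal(s[["sd"]], sqrt(10^2 - 10 * 1^2) / sqrt(9), tolerance = 1e-12) # 3.1623
  expect_equal(summarize_replicates(5), c(mean = 5, sd = 0))
  expect_error(summarize_replicates(numeric(0)), class = "xrfnet_validation_error")
})
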