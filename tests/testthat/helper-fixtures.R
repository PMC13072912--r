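# Shared fixtures, all generated in code at test time.

# small detector for fast unit tests: same windows coverage, default physics
test_detector <- function(...) detector_model(...)

# a tiny deterministic calibration fixture: `n` standards, 1 pellet x 1 repeat
tiny_calibration <- function(n = 6, seed = 11, n_pellets = 1L, n_repeats = 1L,
                             background_cv = 0.05) {
  design <- default_calibration_design()[seq_len(n), ]
  design$n_pellets <- n_pellets
  design$n_repeats <- n_repeats
  simulate_standards(
    design, seed = seed,
    matrix_units = list(
      unit1 = calrose_unit1(background_cv = background_cv),
      unit2 = calrose_unit2(background_cv = background_cv)
    )
  )
}

# fast training settings for unit tests (the full recipe is exercised in the
# acceptance suite)
tiny_spec <- function() net_spec(hidden_sizes = c(16L, 8L), dropout_p = 0.1)
tiny_config <- function(seed = 5L) {
  train_config(learning_rate = 1e-3, n_epochs = 300L, eval_every = 50L,
               seed = seed)
}

# noiseless single-acquisition spectra for a set of (As, Pb) totals
noiseless_spectra <- function(as_totals, pb_totals,
                              matrix = matrix_profile(0, 0, continuum_amplitude = 0,
                                                      background_cv = 0),
                              detector = detector_model()) {
  stopifnot(length(as_totals) == length(pb_totals))
  specs <- lapply(seq_along(as_totals), function(i) {
    expected_spectrum(as_totals[i], pb_totals[i], matrix, detector,
                      standard_id = sprintf("nl%02d", i))
  })
  list(
    spectra = dplyr::bind_rows(specs),
    standards = tibble::tibble(
      standard_id = sprintf("nl%02d", seq_along(as_totals)),
      as_ug_kg = as_totals, pb_ug_kg = pb_totals, role = "train"
    )
  )
}
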