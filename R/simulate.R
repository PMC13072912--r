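#' Characteristic emission lines of As and Pb
#'
#' The line table used by the forward simulator: energies of the principal and
#' secondary emissions, K/L-shell fluorescence yields, and relative in-shell
#' branching. The As K-alpha (10.52 keV) and Pb L-alpha (10.50 keV) lines are
#' separated by only 0.02 keV -- far below benchtop detector resolution --
#' which is the spectral-overlap problem this package addresses. Pb K lines
#' (~74 keV) are excluded: a 50 kV tube cannot excite them.
#'
#' @details Defaults: As K-shell fluorescence yield 0.549, Pb L-shell yield
#'   0.386; the Pb L-beta branch is 1/1.61 of L-alpha (an L-alpha event is
#'   1.61 times more probable); the As K-beta branch is 0.15 of K-alpha, a
#'   typical K-shell ratio.
#' @return A tibble with columns `element`, `label`, `energy_keV`,
#'   `shell_yield`, `branch`.
#' @export
emission_lines <- function() {
  tibble(
    element = c("As", "As", "Pb", "Pb"),
    label = c("Ka", "Kb", "La", "Lb"),
    energy_keV = c(10.52, 11.73, 10.50, 12.62),
    shell_yield = c(0.549, 0.549, 0.386, 0.386),
    branch = c(1, 0.15, 1, 1 / 1.61)
  )
}

#' Benchtop silicon-drift detector model
#'
#' Resolution anchor, channelization and absolute sensitivity of the simulated
#' instrument.
#'
#' @param fwhm_ref_keV Resolution (FWHM, keV) at the reference line; default
#'   0.135 at Mn K-alpha.
#' @param ref_energy_keV Reference line energy; default 5.895 (Mn K-alpha).
#' @param step_keV Channel width (keV).
#' @param grid_lo_keV,grid_hi_keV Simulated energy range; must cover the
#'   feature windows.
#' @param sensitivity Expected net counts per (ug/kg x unit emission weight)
#'   in a 120 s acquisition; the default 8 puts a peak SNR of about 4 on the
#'   9-replicate averaged spectrum of the lowest-As rice standard
#'   (87.82 ug/kg), a weak but identifiable peak.
#' @param live_time_s Acquisition live time (s).
#' @return An object of class `detector_model`.
#' @export
detector_model <- function(fwhm_ref_keV = 0.135, ref_energy_keV = 5.895,
                           step_keV = 0.01, grid_lo_keV = 10.00,
                           grid_hi_keV = 13.20, sensitivity = 8,
                           live_time_s = 120) {
  vals <- c(fwhm_ref_keV, ref_energy_keV, step_keV, sensitivity, live_time_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    xrf_abort("detector parameters must be positive", "validation_error")
  }
  if (grid_hi_keV <= grid_lo_keV) xrf_abort("empty energy range", "grid_error")
  structure(
    list(fwhm_ref_keV = fwhm_ref_keV, ref_energy_keV = ref_energy_keV,
         step_keV = step_keV, grid_lo_keV = grid_lo_keV,
         grid_hi_keV = grid_hi_keV, sensitivity = sensitivity,
         live_time_s = live_time_s),
    class = "detector_model"
  )
}

detector_grid <- function(d) {
  n <- floor((d$grid_hi_keV - d$grid_lo_keV) / d$step_keV + 1e-9) + 1
  energy_grid(d$grid_lo_keV, d$step_keV, n)
}

#' Detector resolution at an arbitrary energy
#'
#' FWHM scales with the square root of energy (Fano counting statistics in a
#' silicon drift detector), anchored at the reference line:
#' `FWHM(E) = fwhm_ref * sqrt(E / ref_energy)`.
#'
#' @param energy_keV Energy (keV), positive.
#' @param detector A [detector_model()].
#' @return FWHM in keV.
#' @examples
#' fwhm_at(5.895, detector_model()) # 0.135, the Mn K-alpha anchor
#' fwhm_at(10.52, detector_model()) # about 0.180 at As K-alpha
#' @export
fwhm_at <- function(energy_keV, detector = detector_model()) {
  if (any(energy_keV <= 0)) xrf_abort("energy must be positive", "domain_error")
  detector$fwhm_ref_keV * sqrt(energy_keV / detector$ref_energy_keV)
}

#' Rice matrix profile
#'
#' Intrinsic As/Pb contamination of a rice unit and its smooth continuum
#' background. The continuum is a single exponential in energy,
#' `amplitude * exp(-decay * (E - 10.5))` expected counts per channel; scatter
#' peaks lie outside the feature windows and are not modelled. Real pellets
#' do not all scatter identically, so the effective continuum amplitude of an
#' individual acquisition varies lognormally around the nominal value with
#' coefficient of variation `background_cv`, while the instrument's recorded
#' background estimate stays at the nominal continuum -- the model has to
#' cope with that mismatch just as it must on a real instrument.
#'
#' @param intrinsic_as,intrinsic_pb Intrinsic concentrations (ug/kg).
#' @param continuum_amplitude Expected continuum counts per channel at
#'   10.5 keV in a 120 s acquisition.
#' @param continuum_decay Exponential decay rate per keV (>= 0).
#' @param background_cv Per-acquisition lognormal CV of the true continuum
#'   amplitude (0 disables the variability).
#' @return An object of class `matrix_profile`.
#' @examples
#' calrose_unit2() # the low-As Calrose rice unit
#' @export
matrix_profile <- function(intrinsic_as, intrinsic_pb,
                           continuum_amplitude = 200, continuum_decay = 0.1,
                           background_cv = 0.05) {
  if (intrinsic_as < 0 || intrinsic_pb < 0 || continuum_amplitude < 0 ||
      continuum_decay < 0 || background_cv < 0) {
    xrf_abort("matrix parameters must be non-negative", "validation_error")
  }
  structure(
    list(intrinsic_as = intrinsic_as, intrinsic_pb = intrinsic_pb,
         continuum_amplitude = continuum_amplitude,
         continuum_decay = continuum_decay, background_cv = background_cv),
    class = "matrix_profile"
  )
}

#' @rdname matrix_profile
#' @export
calrose_unit1 <- function(...) matrix_profile(137.37, 4.26, ...)

#' @rdname matrix_profile
#' @param ... Passed on to [matrix_profile()] (continuum settings).
#' @export
calrose_unit2 <- function(...) matrix_profile(87.82, 3.19, ...)

continuum_at <- function(energy, m, amplitude = m$continuum_amplitude) {
  amplitude * exp(-m$continuum_decay * (energy - 10.5))
}

#' Noiseless expected spectrum of a spiked rice pellet
#'
#' Expected total counts per channel are the matrix continuum plus, for every
#' emission line, `conc * sensitivity * shell_yield * branch` photons spread
#' over the channels by a unit-area Gaussian of width `sigma = FWHM/2.3548`
#' integrated across each channel. Expected counts are linear in each
#' element's concentration; `background_counts` holds the continuum exactly.
#'
#' @param as_total,pb_total Total concentrations (spike plus intrinsic), ug/kg.
#' @param matrix A [matrix_profile()].
#' @param detector A [detector_model()].
#' @param lines Emission-line table, default [emission_lines()].
#' @param standard_id,pellet_id,repeat_id Metadata stamped on the output.
#' @return A spectra tibble (one acquisition) whose `total_counts` are the
#'   noiseless expectations.
#' @export
expected_spectrum <- function(as_total, pb_total, matrix = calrose_unit2(),
                              detector = detector_model(),
                              lines = emission_lines(),
                              standard_id = "expected", pellet_id = 1L,
                              repeat_id = 1L) {
  if (as_total < 0 || pb_total < 0) {
    xrf_abort("concentrations must be non-negative", "validation_error")
  }
  energy <- grid_energies(detector_grid(detector))
  bg <- continuum_at(energy, matrix)
  total <- bg + line_counts(energy, as_total, pb_total, detector, lines)
  tibble(
    standard_id = standard_id, pellet_id = as.integer(pellet_id),
    repeat_id = as.integer(repeat_id), energy_keV = energy,
    total_counts = total, background_counts = bg,
    live_time_s = detector$live_time_s
  )
}

# expected characteristic-line counts per channel (no continuum)
line_counts <- function(energy, as_total, pb_total, detector, lines) {
  step <- detector$step_keV
  out <- numeric(length(energy))
  for (i in seq_len(nrow(lines))) {
    li <- lines[i, ]
    conc <- if (li$element == "As") as_total else pb_total
    if (conc == 0) next
    sigma <- fwhm_at(li$energy_keV, detector) / (2 * sqrt(2 * log(2)))
    area <- conc * detector$sensitivity * li$shell_yield * li$branch
    out <- out + area * (pnorm(energy + step / 2, li$energy_keV, sigma) -
                           pnorm(energy - step / 2, li$energy_keV, sigma))
  }
  out
}

#' Sample a noisy acquisition from an expected spectrum
#'
#' Total counts are drawn channelwise from a Poisson law with the expected
#' totals as means; the background channel is copied noiseless (it stands in
#' for the instrument's background estimate). Reproducible given `seed`.
#'
#' @param expected An expected spectra tibble from [expected_spectrum()].
#' @param seed Integer seed.
#' @return A spectra tibble with integer-valued `total_counts`.
#' @export
sample_spectrum <- function(expected, seed) {
  if (any(expected$total_counts < 0)) {
    xrf_abort("expected counts must be non-negative", "domain_error")
  }
  with_preserved_seed(seed, {
    mutate(expected, total_counts = as.numeric(rpois(n(), .data$total_counts)))
  })
}

# run code under a local RNG state
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic per-acquisition sub-seed, kept inside 32-bit integer range
sub_seed <- function(master, standard_index, pellet, rep) {
  ((as.numeric(master) * 100003 + standard_index * 1009 +
      pellet * 101 + rep) %% 2147483646) + 1
}

#' Default calibration design
#'
#' Twenty-eight standards emulating the published calibration campaign:
#' milled Calrose rice spiked with As and/or Pb over roughly 0-600 ug/kg
#' (total concentration = gravimetric spike + the unit's intrinsic
#' contamination), three pellets per standard analysed in triplicate
#' (9 spectra per standard, 252 in total).
#'
#' @return A design tibble with columns `standard_id`, `spiked_as`,
#'   `spiked_pb`, `matrix_unit`, `n_pellets`, `n_repeats`.
#' @export
default_calibration_design <- function() {
  # As-only ladder on Unit 2 (intrinsic As 87.82), Pb-only ladder on Unit 1
  # (intrinsic As 137.37), and a crossed block covering mixed contamination.
  as_tot <- c(87.82, 150, 220, 280, 341.45, 446.65, 608.57)
  pb_tot <- c(4.26, 75, 150, 208.34, 300, 420.93, 586.27)
  mixed <- expand.grid(as = c(100, 250, 400, 600),
                       pb = c(75, 200, 400, 550))[1:14, ]
  design <- bind_rows(
    tibble(spiked_as = as_tot - 87.82, spiked_pb = 0, matrix_unit = "unit2"),
    tibble(spiked_as = 0, spiked_pb = pb_tot - 4.26, matrix_unit = "unit1"),
    tibble(spiked_as = mixed$as, spiked_pb = mixed$pb, matrix_unit = "unit2")
  )
  design %>%
    mutate(standard_id = sprintf("cal%02d", row_number()),
           n_pellets = 3L, n_repeats = 3L) %>%
    select("standard_id", "spiked_as", "spiked_pb", "matrix_unit",
           "n_pellets", "n_repeats")
}

#' Simulate a set of standards from a design table
#'
#' For each design row the total concentration is the spike plus the assigned
#' matrix unit's intrinsic level; `n_pellets x n_repeats` acquisitions are
#' sampled with deterministic per-acquisition sub-seeds, so any single
#' spectrum is independently reproducible from the master seed.
#'
#' @param design A design tibble as from [default_calibration_design()].
#' @param seed Master integer seed.
#' @param matrix_units Named list of [matrix_profile()]s referenced by the
#'   design's `matrix_unit` column.
#' @param detector A [detector_model()].
#' @param lines Emission-line table.
#' @param role Role label stamped on the standards table.
#' @return A list with elements `spectra` (long tibble) and `standards`
#'   (tibble of total concentrations with the replicate count).
#' @export
simulate_standards <- function(design, seed,
                               matrix_units = list(unit1 = calrose_unit1(),
                                                   unit2 = calrose_unit2()),
                               detector = detector_model(),
                               lines = emission_lines(),
                               role = "train") {
  if (nrow(design) < 1) xrf_abort("design is empty", "config_error")
  if (any(design$spiked_as < 0) || any(design$spiked_pb < 0)) {
    xrf_abort("spikes must be non-negative", "config_error")
  }
  unknown <- setdiff(unique(design$matrix_unit), names(matrix_units))
  if (length(unknown)) {
    xrf_abort(paste0("unknown matrix unit(s): ", paste(unknown, collapse = ", ")),
              "config_error")
  }
  rows <- purrr::pmap(
    list(seq_len(nrow(design)), design$standard_id, design$spiked_as,
         design$spiked_pb, design$matrix_unit, design$n_pellets,
         design$n_repeats),
    function(i, sid, sa, sp, unit, np, nr) {
      m <- matrix_units[[unit]]
      as_tot <- sa + m$intrinsic_as
      pb_tot <- sp + m$intrinsic_pb
      nominal <- expected_spectrum(as_tot, pb_tot, m, detector, lines,
                                   standard_id = sid)
      line_part <- nominal$total_counts - nominal$background_counts
      specs <- purrr::map(seq_len(np), function(pl) {
        purrr::map(seq_len(nr), function(rp) {
          s <- sub_seed(seed, i, pl, rp)
          with_preserved_seed(s, {
            amp_factor <- if (m$background_cv > 0) {
              exp(rnorm(1, 0, sqrt(log(1 + m$background_cv^2))))
            } else 1
            expect_tot <- nominal$background_counts * amp_factor + line_part
            tibble(
              standard_id = sid, pellet_id = pl, repeat_id = rp,
              energy_keV = nominal$energy_keV,
              total_counts = as.numeric(rpois(length(expect_tot), expect_tot)),
              background_counts = nominal$background_counts,
              live_time_s = detector$live_time_s
            )
          })
        })
      })
      list(
        spectra = bind_rows(purrr::flatten(specs)),
        standard = tibble(standard_id = sid, as_ug_kg = as_tot,
                          pb_ug_kg = pb_tot, role = role,
                          n_replicates = np * nr)
      )
    }
  )
  list(
    spectra = bind_rows(purrr::map(rows, "spectra")),
    standards = bind_rows(purrr::map(rows, "standard"))
  )
}

#' Simulate one of the two detection-limit scenarios
#'
#' Ten identical rice standards at 128.97 ug/kg total As; Pb at the matrix
#' intrinsic level only (scenario 1, non-detectable Pb) or at 208.95 ug/kg
#' total (scenario 2, detectable Pb interference). Nine spectra per standard.
#'
#' @param scenario 1 or 2.
#' @param seed Master integer seed.
#' @param matrix A [matrix_profile()]; the scenario concentrations are totals,
#'   so the unit's intrinsic levels are already included.
#' @param detector A [detector_model()].
#' @param lines Emission-line table.
#' @return A list with `spectra` and `standards` tibbles (10 standards,
#'   90 spectra).
#' @export
simulate_scenario <- function(scenario, seed, matrix = calrose_unit2(),
                              detector = detector_model(),
                              lines = emission_lines()) {
  if (!scenario %in% c(1, 2)) {
    xrf_abort("scenario must be 1 or 2", "config_error")
  }
  as_total <- 128.97
  pb_total <- if (scenario == 1) matrix$intrinsic_pb else 208.95
  design <- tibble(
    standard_id = sprintf("sc%d_%02d", scenario, 1:10),
    spiked_as = as_total - matrix$intrinsic_as,
    spiked_pb = pb_total - matrix$intrinsic_pb,
    matrix_unit = "m", n_pellets = 3L, n_repeats = 3L
  )
  simulate_standards(design, seed, matrix_units = list(m = matrix),
                     detector = detector, lines = lines,
                     role = paste0("scenario", scenario))
}

#' Validation-set design emulating the published study
#'
#' One certified reference material (rice flour, 263.63 ug/kg As as measured
#' by the reference ICP-MS method), eleven commercial rice and rice-based
#' foods spanning 56.84-296.72 ug/kg As with trace Pb, and twelve Pb-spiked
#' points (four commercial matrices at three Pb levels of roughly
#' 75-400 ug/kg).
#'
#' @return A tibble with columns `sample`, `category`, `as_ug_kg`, `pb_ug_kg`.
#' @export
validation_design <- function() {
  commercial <- tibble(
    sample = c("Brown Rice Cereal #1", "Rice Cereal #1", "White Rice",
               "Brown Rice", "Rice Cereal #2", "Rice Rusks #1",
               "Rice Cereal #3", "Rice Puffs #1", "Rice Rusks #2",
               "Rice Puffs #2", "Rice Wafer"),
    as_ug_kg = c(296.72, 248.03, 225.85, 183.10, 154.10, 127.69, 125.97,
                 101.71, 99.06, 73.10, 56.84),
    pb_ug_kg = c(0.00, 0.00, 0.00, 0.18, 0.00, 1.23, 0.00, 0.00, 0.00,
                 0.00, 28.71),
    category = "commercial"
  )
  spiked_base <- commercial %>%
    filter(.data$sample %in% c("Rice Cereal #1", "Brown Rice",
                               "Rice Cereal #2", "Rice Puffs #1"))
  spiked <- purrr::map_dfr(c(75, 200, 400), function(lvl) {
    spiked_base %>%
      mutate(sample = sprintf("%s + Pb %d", .data$sample, lvl),
             pb_ug_kg = .data$pb_ug_kg + lvl,
             category = "pb_spiked")
  })
  bind_rows(
    tibble(sample = "CRM (ERM-BC211)", as_ug_kg = 263.63, pb_ug_kg = 5.28,
           category = "crm"),
    commercial, spiked
  ) %>% select("sample", "category", "as_ug_kg", "pb_ug_kg")
}

#' Simulate the validation set
#'
#' Each validation sample becomes a pelletized standard measured as 3 pellets
#' x 3 repeats on its own matrix (the sample's As/Pb content is the matrix's
#' intrinsic level -- nothing is spiked beyond the design concentrations).
#'
#' @param seed Master integer seed.
#' @param design Validation design tibble, default [validation_design()].
#' @param detector A [detector_model()].
#' @param lines Emission-line table.
#' @param continuum_amplitude,continuum_decay,background_cv Continuum settings
#'   shared by all validation matrices.
#' @return A list with `spectra`, `standards` and `samples` (the design with
#'   `standard_id` attached).
#' @export
simulate_validation <- function(seed, design = validation_design(),
                                detector = detector_model(),
                                lines = emission_lines(),
                                continuum_amplitude = 200,
                                continuum_decay = 0.1, background_cv = 0.05) {
  design <- mutate(design, standard_id = sprintf("val%02d", row_number()))
  units <- purrr::map(seq_len(nrow(design)), function(i) {
    matrix_profile(design$as_ug_kg[i], design$pb_ug_kg[i],
                   continuum_amplitude, continuum_decay, background_cv)
  })
  names(units) <- design$standard_id
  sim_design <- tibble(
    standard_id = design$standard_id, spiked_as = 0, spiked_pb = 0,
    matrix_unit = design$standard_id, n_pellets = 3L, n_repeats = 3L
  )
  out <- simulate_standards(sim_design, seed, matrix_units = units,
                            detector = detector, lines = lines,
                            role = "validation")
  out$samples <- design
  out
}

#' Held-out probe design for parameter recovery
#'
#' A crossed grid using one common set of concentration levels for both
#' elements, spanning the calibration range and lying inside both elements'
#' training support. Recovery metrics compared between elements are only
#' meaningful on matched levels, which the validation design (wide bimodal
#' Pb, narrower As) does not provide.
#'
#' @return A design tibble usable with [simulate_standards()] via a dedicated
#'   matrix unit per row.
#' @export
probe_design <- function() {
  levels <- c(100, 260, 420, 580)
  grid <- expand.grid(as = levels, pb = levels)
  tibble(
    standard_id = sprintf("probe%02d", seq_len(nrow(grid))),
    as_ug_kg = grid$as, pb_ug_kg = grid$pb
  )
}

#' Simulate the probe set
#'
#' @param seed Master integer seed.
#' @param design Probe design tibble.
#' @inheritParams simulate_validation
#' @return A list with `spectra` and `standards`.
#' @export
simulate_probe <- function(seed, design = probe_design(),
                           detector = detector_model(),
                           lines = emission_lines(),
                           continuum_amplitude = 200, continuum_decay = 0.1,
                           background_cv = 0.05) {
  units <- purrr::map(seq_len(nrow(design)), function(i) {
    matrix_profile(design$as_ug_kg[i], design$pb_ug_kg[i],
                   continuum_amplitude, continuum_decay, background_cv)
  })
  names(units) <- design$standard_id
  sim_design <- tibble(
    standard_id = design$standard_id, spiked_as = 0, spiked_pb = 0,
    matrix_unit = design$standard_id, n_pellets = 3L, n_repeats = 3L
  )
  simulate_standards(sim_design, seed, matrix_units = units,
                     detector = detector, lines = lines, role = "probe")
}
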