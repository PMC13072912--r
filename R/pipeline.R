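#' Run configuration
#'
#' A single structured configuration drives every pipeline stage so that a
#' whole method study (simulate -> calibrate -> limits -> validate) is
#' reproducible from one file and one master seed.
#'
#' @param output_dir Directory all stage outputs are written to.
#' @param seed Master integer seed; each stage derives its own deterministic
#'   sub-seeds from it.
#' @param region A [region_spec()].
#' @param spec A [net_spec()].
#' @param config A [train_config()] (its `seed` is overridden by the master
#'   seed).
#' @param detector A [detector_model()].
#' @param z_threshold Outlier-exclusion threshold on `|z|`.
#' @param agreement_pct Validation agreement band half-width (percent).
#' @param limits_n `n` passed to [detection_limits()].
#' @param pb_reference_loq LOQ (ug/kg) used to decide whether a reference Pb
#'   value is quantifiable in validation; default 6.59, the blank-based LOQ
#'   of the reference ICP-MS method.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(output_dir, seed = 1L, region = region_spec(),
                       spec = net_spec(), config = train_config(),
                       detector = detector_model(), z_threshold = 2.5,
                       agreement_pct = 20, limits_n = 3,
                       pb_reference_loq = 6.59) {
  config$seed <- as.integer(seed)
  structure(
    list(output_dir = output_dir, seed = as.integer(seed), region = region,
         spec = spec, config = config, detector = detector,
         z_threshold = z_threshold, agreement_pct = agreement_pct,
         limits_n = limits_n, pb_reference_loq = pb_reference_loq),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Recognised keys (all optional except `output_dir`): `seed`, `output_dir`,
#' `region` (list of `[lo, hi]` pairs), `hidden_sizes`, `dropout_p`,
#' `learning_rate`, `n_epochs`, `eval_every`, `detector` (named fields of
#' [detector_model()]), `z_threshold`, `agreement_pct`, `limits_n`,
#' `pb_reference_loq`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) xrf_abort(paste0("no such file: ", path), "io_error")
  y <- yaml::read_yaml(path)
  if (is.null(y$output_dir)) xrf_abort("config needs output_dir", "config_error")
  region <- if (is.null(y$region)) region_spec() else region_spec(y$region)
  spec <- net_spec(
    hidden_sizes = y$hidden_sizes %||% c(256L, 128L),
    dropout_p = y$dropout_p %||% 0.1
  )
  config <- train_config(
    learning_rate = y$learning_rate %||% 1e-5,
    n_epochs = y$n_epochs %||% 10000L,
    eval_every = y$eval_every %||% 500L
  )
  detector <- do.call(detector_model, y$detector %||% list())
  run_config(
    output_dir = y$output_dir, seed = y$seed %||% 1L, region = region,
    spec = spec, config = config, detector = detector,
    z_threshold = y$z_threshold %||% 2.5,
    agreement_pct = y$agreement_pct %||% 20,
    limits_n = y$limits_n %||% 3,
    pb_reference_loq = y$pb_reference_loq %||% 6.59
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_path <- function(rc, ...) file.path(rc$output_dir, ...)

# append stage entries to the run manifest
update_manifest <- function(rc, stage, files, elapsed_s) {
  path <- stage_path(rc, "manifest.json")
  manifest <- if (file.exists(path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    list(seed = rc$seed,
         software = paste0("xrfnet ", as.character(utils::packageVersion("xrfnet"))),
         stages = list())
  }
  manifest$stages[[stage]] <- list(
    elapsed_s = round(elapsed_s, 3),
    files = as.list(basename(files))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate the full study's input data
#'
#' Writes the 28-standard calibration design (252 spectra), the two
#' detection-limit scenario sets (90 spectra each) and the synthetic
#' validation set in the package's CSV dialects, plus a run manifest.
#' Rerunning with the same configuration reproduces byte-identical files.
#'
#' @param rc A [run_config()].
#' @param design Calibration design tibble; default
#'   [default_calibration_design()].
#' @return Invisibly, the tibble of written files.
#' @export
run_simulate <- function(rc, design = default_calibration_design()) {
  if (nrow(design) == 0) xrf_abort("empty calibration design", "config_error")
  dir.create(rc$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]

  cal <- simulate_standards(design, seed = rc$seed, detector = rc$detector)
  sc1 <- simulate_scenario(1, seed = rc$seed + 1, detector = rc$detector)
  sc2 <- simulate_scenario(2, seed = rc$seed + 2, detector = rc$detector)
  val <- simulate_validation(seed = rc$seed + 3, detector = rc$detector)

  files <- c(
    calibration_spectra = stage_path(rc, "calibration_spectra.csv"),
    calibration_standards = stage_path(rc, "calibration_standards.csv"),
    scenario1_spectra = stage_path(rc, "scenario1_spectra.csv"),
    scenario1_standards = stage_path(rc, "scenario1_standards.csv"),
    scenario2_spectra = stage_path(rc, "scenario2_spectra.csv"),
    scenario2_standards = stage_path(rc, "scenario2_standards.csv"),
    validation_spectra = stage_path(rc, "validation_spectra.csv"),
    validation_standards = stage_path(rc, "validation_standards.csv"),
    validation_samples = stage_path(rc, "validation_samples.csv")
  )
  write_spectra(cal$spectra, files[["calibration_spectra"]])
  write_standards(cal$standards, files[["calibration_standards"]])
  write_spectra(sc1$spectra, files[["scenario1_spectra"]])
  write_standards(sc1$standards, files[["scenario1_standards"]])
  write_spectra(sc2$spectra, files[["scenario2_spectra"]])
  write_standards(sc2$standards, files[["scenario2_standards"]])
  write_spectra(val$spectra, files[["validation_spectra"]])
  write_standards(val$standards, files[["validation_standards"]])
  readr::write_csv(val$samples, files[["validation_samples"]], progress = FALSE)

  update_manifest(rc, "simulate", files, proc.time()[["elapsed"]] - t0)
  invisible(tibble(name = names(files), path = unname(files)))
}

#' Calibrate the model from the simulated (or measured) files
#'
#' Reads the calibration spectra/standards and the validation set written by
#' [run_simulate()], runs [fit_calibration()] (validation spectra act as the
#' checkpointing test set), and persists the model artifact, the outlier
#' ledger, the per-standard calibration table (predicted vs actual with
#' spreads) and the metrics JSON.
#'
#' @param rc A [run_config()].
#' @return The `xrf_calibration` object, invisibly.
#' @export
run_calibrate <- function(rc) {
  t0 <- proc.time()[["elapsed"]]
  standards <- read_standards(stage_path(rc, "calibration_standards.csv"))
  spectra <- read_spectra(stage_path(rc, "calibration_spectra.csv"))
  val_standards <- read_standards(stage_path(rc, "validation_standards.csv"))
  if (nrow(val_standards) == 0) {
    xrf_abort("no validation (test-role) standards found", "config_error")
  }
  val_spectra <- read_spectra(stage_path(rc, "validation_spectra.csv"))
  test_ft <- assemble_dataset(val_spectra, val_standards, rc$region)

  fit <- fit_calibration(standards, spectra, test_ft, region = rc$region,
                         spec = rc$spec, config = rc$config,
                         z_threshold = rc$z_threshold)

  files <- c(
    model = stage_path(rc, "model.rds"),
    ledger = stage_path(rc, "outlier_ledger.csv"),
    calibration = stage_path(rc, "calibration_table.csv"),
    metrics = stage_path(rc, "calibration_metrics.json")
  )
  write_model(fit$model, files[["model"]])
  readr::write_csv(fit$ledger, files[["ledger"]], progress = FALSE)
  readr::write_csv(fit$calibration, files[["calibration"]], progress = FALSE)
  jsonlite::write_json(fit$metrics, files[["metrics"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  update_manifest(rc, "calibrate", files, proc.time()[["elapsed"]] - t0)
  invisible(fit)
}

#' Detection/quantification limits for one analytical scenario
#'
#' Predicts the scenario standards with the persisted model, aggregates the
#' replicate spectra per standard, and computes the per-element limit
#' estimates. Scenario 1 (non-detectable Pb) reports an As row only;
#' scenario 2 reports As and Pb.
#'
#' @param rc A [run_config()].
#' @param scenario 1 or 2.
#' @return The limits tibble (one row per reported element), invisibly
#'   written to `limits_scenario<k>.csv` / `.json`.
#' @export
run_limits <- function(rc, scenario) {
  if (!scenario %in% c(1, 2)) xrf_abort("scenario must be 1 or 2", "config_error")
  t0 <- proc.time()[["elapsed"]]
  model <- read_model(stage_path(rc, "model.rds"))
  standards <- read_standards(stage_path(rc, sprintf("scenario%d_standards.csv", scenario)))
  spectra <- read_spectra(stage_path(rc, sprintf("scenario%d_spectra.csv", scenario)))
  if (nrow(standards) != 10) {
    warning(sprintf("scenario %d has %d standards (10 expected); proceeding",
                    scenario, nrow(standards)))
  }
  ft <- assemble_dataset(spectra, standards, model$region %||% rc$region)
  agg <- aggregate_by_standard(predict(model, ft))

  out <- detection_limits(agg$as_mean, n = rc$limits_n,
                          actual = standards$as_ug_kg[1], element = "As")
  if (scenario == 2) {
    out <- bind_rows(
      out,
      detection_limits(agg$pb_mean, n = rc$limits_n,
                       actual = standards$pb_ug_kg[1], element = "Pb")
    )
  }
  out <- mutate(out, scenario = scenario, .before = 1)

  files <- c(
    csv = stage_path(rc, sprintf("limits_scenario%d.csv", scenario)),
    json = stage_path(rc, sprintf("limits_scenario%d.json", scenario)),
    preds = stage_path(rc, sprintf("limits_scenario%d_predictions.csv", scenario))
  )
  readr::write_csv(out, files[["csv"]], progress = FALSE)
  jsonlite::write_json(out, files[["json"]], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  readr::write_csv(agg, files[["preds"]], progress = FALSE)
  update_manifest(rc, sprintf("limits%d", scenario), files,
                  proc.time()[["elapsed"]] - t0)
  invisible(out)
}

#' Validate the calibrated model against reference concentrations
#'
#' Predicts every validation standard, aggregates the nine replicate spectra,
#' and scores each element determination against its reference value with
#' the +/-20 percent rule. The As agreement threshold uses the scenario-1
#' As LOQ when available; reference Pb values are judged quantifiable
#' against the reference-method LOQ. Per-category mean/median error
#' summaries are written alongside the per-sample records.
#'
#' @param rc A [run_config()].
#' @return A list with `records` and `summary` tibbles, invisibly.
#' @export
run_validate <- function(rc) {
  t0 <- proc.time()[["elapsed"]]
  model <- read_model(stage_path(rc, "model.rds"))
  standards <- read_standards(stage_path(rc, "validation_standards.csv"))
  spectra <- read_spectra(stage_path(rc, "validation_spectra.csv"))
  samples <- readr::read_csv(stage_path(rc, "validation_samples.csv"),
                             show_col_types = FALSE, progress = FALSE)

  known <- standards$standard_id[!is.na(standards$as_ug_kg)]
  dropped <- setdiff(unique(spectra$standard_id), known)
  if (length(dropped)) {
    warning(sprintf("excluding %d sample(s) without known concentrations: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    spectra <- filter(spectra, .data$standard_id %in% known)
  }
  ft <- assemble_dataset(spectra, standards, model$region %||% rc$region)
  agg <- aggregate_by_standard(predict(model, ft)) %>%
    left_join(select(samples, "standard_id", "sample", "category"),
              by = "standard_id")

  as_loq_path <- stage_path(rc, "limits_scenario1.csv")
  as_loq <- if (file.exists(as_loq_path)) {
    readr::read_csv(as_loq_path, show_col_types = FALSE, progress = FALSE)$loq[1]
  } else 0

  records <- bind_rows(purrr::map(seq_len(nrow(agg)), function(i) {
    bind_rows(
      assess_agreement(agg$as_mean[i], agg$as_ug_kg[i],
                       threshold_pct = rc$agreement_pct, loq = as_loq,
                       sample = agg$sample[i], element = "As"),
      assess_agreement(agg$pb_mean[i], agg$pb_ug_kg[i],
                       threshold_pct = rc$agreement_pct,
                       loq = rc$pb_reference_loq,
                       sample = agg$sample[i], element = "Pb")
    ) %>% mutate(category = agg$category[i])
  }))
  summary <- category_summary(records)

  files <- c(
    records = stage_path(rc, "validation_records.csv"),
    summary = stage_path(rc, "validation_summary.csv"),
    json = stage_path(rc, "validation_summary.json")
  )
  readr::write_csv(records, files[["records"]], progress = FALSE)
  readr::write_csv(summary, files[["summary"]], progress = FALSE)
  jsonlite::write_json(summary, files[["json"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  update_manifest(rc, "validate", files, proc.time()[["elapsed"]] - t0)
  invisible(list(records = records, summary = summary))
}

#' Run the whole pipeline
#'
#' simulate -> calibrate -> limits (both scenarios) -> validate, end to end
#' under one master seed.
#'
#' @param rc A [run_config()].
#' @return A list with the calibration fit, both limits tibbles and the
#'   validation results, invisibly.
#' @export
run_all <- function(rc) {
  run_simulate(rc)
  fit <- run_calibrate(rc)
  l1 <- run_limits(rc, 1)
  l2 <- run_limits(rc, 2)
  val <- run_validate(rc)
  invisible(list(fit = fit, limits1 = l1, limits2 = l2, validation = val))
}
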