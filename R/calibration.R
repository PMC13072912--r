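#' Aggregate per-spectrum predictions to per-standard means
#'
#' Reported predictions are the average of a standard's replicate spectra
#' (n = 9 in the reference design); the spread is the sample standard
#' deviation via [summarize_replicates()].
#'
#' @param preds A prediction tibble from [predict.xrf_ann()] holding
#'   `standard_id`, `as_pred`, `pb_pred` (and, if present, the known
#'   `as_ug_kg`, `pb_ug_kg`, which are carried through).
#' @return One row per standard: `as_mean`, `as_sd`, `pb_mean`, `pb_sd`,
#'   `n_spectra`.
#' @export
aggregate_by_standard <- function(preds) {
  if (!"standard_id" %in% names(preds)) {
    xrf_abort("`preds` must have a standard_id column", "validation_error")
  }
  has_targets <- all(c("as_ug_kg", "pb_ug_kg") %in% names(preds))
  out <- preds %>%
    group_by(.data$standard_id) %>%
    summarise(
      as_mean = summarize_replicates(.data$as_pred)[["mean"]],
      as_sd = summarize_replicates(.data$as_pred)[["sd"]],
      pb_mean = summarize_replicates(.data$pb_pred)[["mean"]],
      pb_sd = summarize_replicates(.data$pb_pred)[["sd"]],
      n_spectra = dplyr::n(),
      .groups = "drop"
    )
  if (has_targets) {
    out <- preds %>%
      group_by(.data$standard_id) %>%
      summarise(as_ug_kg = .data$as_ug_kg[1], pb_ug_kg = .data$pb_ug_kg[1],
                .groups = "drop") %>%
      left_join(out, ., by = "standard_id")
  }
  out
}

#' Residual z-scores for outlier screening
#'
#' `z = r / sd(r)` with the sample standard deviation (divisor n - 1) of the
#' residual vector. The numerator is deliberately not mean-centred -- the
#' screening rule divides each raw residual by the spread of all residuals,
#' which is statistically unusual but is exactly the published rule.
#'
#' @param residuals Numeric vector of per-standard residuals
#'   (predicted mean - actual), length >= 2.
#' @return Numeric vector of z-scores, same length.
#' @examples
#' residual_zscores(c(3, -3)) # 0.7071 -0.7071
#' @export
residual_zscores <- function(residuals) {
  if (length(residuals) < 2) {
    xrf_abort("at least two residuals are required", "validation_error")
  }
  s <- sd(residuals)
  if (s == 0) {
    xrf_abort("residual spread is zero; z-scores are undefined",
              "degenerate_spread_error")
  }
  residuals / s
}

#' Fit the calibration model with residual outlier screening
#'
#' The full two-pass procedure: (1) assemble the training feature table;
#' (2) preliminary training; (3) per-standard residuals
#' (mean prediction - actual) for each element; (4) residual z-scores;
#' (5) exclusion of every standard with `|z| > z_threshold` on either
#' element; (6) retraining on the remainder. The outlier screen runs exactly
#' once, before the final model is fitted.
#'
#' @param standards Standards tibble (`standard_id`, `as_ug_kg`, `pb_ug_kg`).
#' @param spectra Spectra tibble covering those standards.
#' @param test Feature table used for checkpoint evaluation in both passes --
#'   an independently simulated or measured validation set, never a split of
#'   the training standards.
#' @param region A [region_spec()].
#' @param spec A [net_spec()].
#' @param config A [train_config()].
#' @param z_threshold Exclusion threshold on `|z|`; default 2.5.
#' @param working_range Optional named vector `c(As = , Pb = )` of working
#'   concentration ranges (ug/kg) for the relative SEC; defaults to the span
#'   of the retained standards per element.
#' @return An object of class `xrf_calibration`: `model` (final `xrf_ann`),
#'   `prelim_model`, `ledger` (per standard and element: residual, z,
#'   excluded), `metrics` (per element [calibration_metrics()]),
#'   `calibration` (per-standard means and spreads of the final model).
#' @export
fit_calibration <- function(standards, spectra, test, region = region_spec(),
                            spec = net_spec(), config = train_config(),
                            z_threshold = 2.5, working_range = NULL) {
  if (nrow(standards) < 5) {
    xrf_abort("at least 5 standards are required", "validation_error")
  }
  train_ft <- assemble_dataset(spectra, standards, region)

  prelim <- ann_train(train_ft, test, spec, config)
  agg <- aggregate_by_standard(predict(prelim, train_ft))

  ledger <- agg %>%
    tidyr::pivot_longer(
      cols = c("as_mean", "pb_mean"), names_to = "element", values_to = "mean_pred"
    ) %>%
    mutate(
      element = ifelse(.data$element == "as_mean", "As", "Pb"),
      actual = ifelse(.data$element == "As", .data$as_ug_kg, .data$pb_ug_kg),
      residual = .data$mean_pred - .data$actual
    ) %>%
    select("standard_id", "element", "actual", "mean_pred", "residual") %>%
    group_by(.data$element) %>%
    mutate(z = residual_zscores(.data$residual)) %>%
    ungroup() %>%
    mutate(flagged = abs(.data$z) > z_threshold)

  excluded_ids <- unique(ledger$standard_id[ledger$flagged])
  ledger <- mutate(ledger, excluded = .data$standard_id %in% excluded_ids)
  keep <- standards %>% filter(!.data$standard_id %in% excluded_ids)
  if (nrow(keep) == 0) {
    xrf_abort("the outlier screen excluded every standard", "procedure_error")
  }
  keep_spectra <- spectra %>% filter(.data$standard_id %in% keep$standard_id)
  final_ft <- assemble_dataset(keep_spectra, keep, region)
  final <- ann_train(final_ft, test, spec, config)

  cal <- aggregate_by_standard(predict(final, final_ft))
  metrics <- bind_rows(
    calibration_metrics(cal$as_mean, cal$as_ug_kg,
                        working_range = working_range[["As"]]) %>%
      mutate(element = "As", .before = 1),
    calibration_metrics(cal$pb_mean, cal$pb_ug_kg,
                        working_range = working_range[["Pb"]]) %>%
      mutate(element = "Pb", .before = 1)
  )

  structure(
    list(model = final, prelim_model = prelim, ledger = ledger,
         metrics = metrics, calibration = cal, z_threshold = z_threshold,
         excluded = excluded_ids),
    class = "xrf_calibration"
  )
}

#' @export
print.xrf_calibration <- function(x, ...) {
  cat(sprintf(
    "<xrf_calibration> %d standards retained, %d excluded (|z| > %.2g)\n",
    nrow(x$calibration), length(x$excluded), x$z_threshold))
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}

#' @describeIn fit_calibration The outlier ledger as a tibble.
#' @param x An `xrf_calibration` object.
#' @param ... Unused.
#' @export
tidy.xrf_calibration <- function(x, ...) x$ledger

#' @describeIn fit_calibration Per-element calibration metrics (R-squared,
#'   SEC, relative SEC, regression slope/intercept).
#' @export
glance.xrf_calibration <- function(x, ...) x$metrics

#' @describeIn fit_calibration Predicted-vs-actual calibration plot with
#'   replicate-spread error bars, one panel per element.
#' @param object An `xrf_calibration` object.
#' @export
autoplot.xrf_calibration <- function(object, ...) {
  cal <- object$calibration
  df <- bind_rows(
    tibble(element = "As", actual = cal$as_ug_kg, predicted = cal$as_mean,
           spread = cal$as_sd),
    tibble(element = "Pb", actual = cal$pb_ug_kg, predicted = cal$pb_mean,
           spread = cal$pb_sd)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$actual, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$predicted - .data$spread,
                                        ymax = .data$predicted + .data$spread),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::facet_wrap(~element, scales = "free") +
    ggplot2::labs(x = "Actual concentration (ug/kg)",
                  y = "Predicted concentration (ug/kg)") +
    ggplot2::theme_minimal()
}
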