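#' Calibration metrics: R-squared, SEC, regression line
#'
#' The goodness-of-fit battery reported for a calibration set: the R-squared
#' of the predicted-versus-actual regression (squared Pearson correlation,
#' identical to the OLS R-squared of that line), the standard error of
#' calibration `SEC = sqrt(sum((pred - actual)^2) / (N - ddof))` over
#' per-standard mean predictions, the SEC as a percentage of the working
#' concentration range, and the OLS slope/intercept of predicted on actual.
#'
#' @param predicted Per-standard mean predictions (ug/kg).
#' @param actual Known concentrations (ug/kg), same length, >= 3 values with
#'   non-zero spread.
#' @param working_range Working concentration range (ug/kg) used as the
#'   denominator of the relative SEC; defaults to `max(actual) - min(actual)`.
#' @param ddof Degrees-of-freedom correction in the SEC divisor `N - ddof`;
#'   default 1, the common chemometrics convention.
#' @return A one-row tibble: `r2`, `sec`, `relative_sec`, `slope`,
#'   `intercept`, `n`.
#' @examples
#' calibration_metrics(c(10, 20, 30), c(10, 20, 30))$r2 # 1
#' @export
calibration_metrics <- function(predicted, actual, working_range = NULL,
                                ddof = 1) {
  if (length(predicted) != length(actual)) {
    xrf_abort("predicted and actual differ in length", "validation_error")
  }
  n <- length(actual)
  if (n < 3) xrf_abort("at least 3 standards are required", "validation_error")
  if (sd(actual) == 0) {
    xrf_abort("actual concentrations have zero variance", "degenerate_error")
  }
  if (is.null(working_range)) working_range <- max(actual) - min(actual)
  fit <- stats::lm(predicted ~ actual)
  sec <- sqrt(sum((predicted - actual)^2) / (n - ddof))
  tibble(
    r2 = stats::cor(predicted, actual)^2,
    sec = sec,
    relative_sec = 100 * sec / working_range,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n = n
  )
}

#' Predictive R-squared of held-out recovery
#'
#' `1 - SS_res / SS_tot` of predictions against known values -- the
#' coefficient-of-determination convention of scikit-learn's `r2_score`,
#' which penalizes predictive bias as well as scatter. This is the metric
#' used to compare parameter recovery between elements on held-out
#' standards; the calibration-table R-squared of [calibration_metrics()] is
#' instead the regression R-squared of the calibration plot.
#'
#' @param predicted,actual Numeric vectors of equal length; `actual` must
#'   have non-zero spread.
#' @return A scalar; 1 for perfect recovery, can be negative for predictions
#'   worse than the mean.
#' @export
recovery_r2 <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    xrf_abort("predicted and actual differ in length", "validation_error")
  }
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) xrf_abort("actual values have zero spread", "degenerate_error")
  1 - sum((predicted - actual)^2) / ss_tot
}

#' Eurachem replicate-based detection and quantification limits
#'
#' From the spread of replicate predicted concentrations of one standard
#' analysed many times: `LOD = 3 * s0 / sqrt(n)` and `LOQ = kQ * s0 / sqrt(n)`
#' where `s0` is the sample standard deviation of the predictions, `n` is the
#' number of replicate observations averaged when reporting a result, and
#' `kQ = 10` is the default IUPAC factor (a 10 percent RSD requirement).
#' Predictive bias is `mean(predictions) - actual`.
#'
#' @param predictions Per-standard mean predictions (ug/kg) of the replicate
#'   standards (10 in the reference design), length >= 2.
#' @param n Number of replicate observations averaged when reporting; the
#'   default 3 reproduces the published limit arithmetic (three pellets).
#' @param kQ IUPAC quantification factor, default 10.
#' @param actual Known concentration of the replicated standard (ug/kg).
#' @param element Optional element label carried into the output.
#' @return A one-row tibble: `element`, `actual`, `mean_pred`, `bias_abs`,
#'   `bias_pct`, `s0`, `n`, `kQ`, `lod`, `loq`.
#' @examples
#' detection_limits(rnorm(10, 113.69, 9.39), n = 3, actual = 128.97)
#' @export
detection_limits <- function(predictions, n = 3, kQ = 10, actual,
                             element = NA_character_) {
  if (length(predictions) < 2) {
    xrf_abort("at least two predictions are required", "validation_error")
  }
  if (n < 1) xrf_abort("n must be >= 1", "domain_error")
  s0 <- sd(predictions)
  mean_pred <- mean(predictions)
  tibble(
    element = element,
    actual = actual,
    mean_pred = mean_pred,
    bias_abs = mean_pred - actual,
    bias_pct = if (actual > 0) 100 * (mean_pred - actual) / actual else NA_real_,
    s0 = s0, n = n, kQ = kQ,
    lod = 3 * s0 / sqrt(n),
    loq = kQ * s0 / sqrt(n)
  )
}

#' Blank-based LOQ of the reference ICP-MS method
#'
#' `LOQ = 10 * sigma_S / b` with `sigma_S` the standard deviation of the
#' sample blanks in signal units and `b` the slope of the calibration curve
#' (signal per concentration).
#'
#' @param blank_sd Non-negative standard deviation of the sample blanks
#'   (signal units).
#' @param slope Calibration-curve slope, > 0.
#' @return LOQ in concentration units.
#' @examples
#' icp_loq(0.659, 1) # 6.59
#' @export
icp_loq <- function(blank_sd, slope) {
  if (slope <= 0) xrf_abort("slope must be positive", "domain_error")
  if (blank_sd < 0) xrf_abort("blank_sd must be non-negative", "validation_error")
  10 * blank_sd / slope
}

#' Agreement of a predicted concentration with its reference value
#'
#' The validation rule: a determination agrees when the percent error
#' `100 * (pred - actual) / actual` lies within the +/-20 percent band.
#' Percent error (and hence agreement) is only meaningful when the reference
#' value itself is quantifiable (`actual >= loq`); below the LOQ only the
#' absolute error in ug/kg is reported and the agreement flag is NA.
#'
#' @param pred,actual Predicted and reference concentrations (ug/kg);
#'   `actual >= 0`.
#' @param threshold_pct Agreement band half-width in percent, default 20.
#' @param loq Applicable limit of quantification for the element (ug/kg);
#'   default 0 treats every reference value as quantifiable.
#' @param sample,element Optional labels carried into the record.
#' @return A one-row tibble: `sample`, `element`, `predicted`, `actual`,
#'   `error_abs`, `error_pct`, `quantifiable`, `agrees`.
#' @examples
#' assess_agreement(209.50, 260) # error -19.42 percent, agrees
#' @export
assess_agreement <- function(pred, actual, threshold_pct = 20, loq = 0,
                             sample = NA_character_, element = NA_character_) {
  if (actual < 0) xrf_abort("actual must be non-negative", "validation_error")
  quantifiable <- actual >= loq & actual > 0
  error_abs <- pred - actual
  error_pct <- if (actual > 0) 100 * error_abs / actual else NA_real_
  tibble(
    sample = sample, element = element,
    predicted = pred, actual = actual,
    error_abs = error_abs, error_pct = error_pct,
    quantifiable = quantifiable,
    agrees = if (quantifiable) abs(error_pct) <= threshold_pct else NA
  )
}

#' Per-category error summaries of validation records
#'
#' Mean and median absolute error per element and sample category. When
#' every record of a category-element cell is quantifiable the summary is of
#' absolute percent errors (unit `%`); otherwise the absolute errors in
#' ug/kg are summarised instead (the published convention for trace-Pb
#' samples below the LOQ). The median of an even count is the midpoint of
#' the two central values.
#'
#' @param records A tibble of agreement records ([assess_agreement()] rows
#'   plus a `category` column).
#' @return A tibble: `category`, `element`, `n`, `unit`, `mean_abs_error`,
#'   `median_abs_error`, `n_agree` (count of agreeing records among the
#'   quantifiable ones).
#' @export
category_summary <- function(records) {
  if (!all(c("category", "element") %in% names(records))) {
    xrf_abort("records need category and element columns", "validation_error")
  }
  if (nrow(records) == 0) xrf_abort("no records", "validation_error")
  records %>%
    group_by(.data$category, .data$element) %>%
    summarise(
      n = dplyr::n(),
      unit = if (all(.data$quantifiable)) "%" else "ug/kg",
      mean_abs_error = if (all(.data$quantifiable)) {
        mean(abs(.data$error_pct))
      } else mean(abs(.data$error_abs)),
      median_abs_error = if (all(.data$quantifiable)) {
        median(abs(.data$error_pct))
      } else median(abs(.data$error_abs)),
      n_agree = sum(.data$agrees, na.rm = TRUE),
      .groups = "drop"
    )
}
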