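test_that("calibration metrics recover the closed-form cases", {
  actual <- c(50, 150, 250, 350, 450)

  ident <- calibration_metrics(actual, actual)
  expect_equal(ident$r2, 1)
  expect_equal(ident$sec, 0)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)

  shifted <- calibration_metrics(actual + 10, actual)
  expect_equal(shifted$r2, 1)
  expect_equal(shifted$slope, 1)
  expect_equal(shifted$intercept, 10)
  # constant +10 residuals with the N-1 divisor
  n <- length(actual)
  expect_equal(shifted$sec, 10 * sqrt(n / (n - 1)), tolerance = 1e-12)
  expect_equal(calibration_metrics(actual + 10, actual, ddof = 0)$sec, 10)

  # the published As pair: SEC 41.20 over a 611.3 ug/kg working range
  m <- calibration_metrics(actual + 1, actual, working_range = 611.3)
  expect_equal(100 * 41.20 / 611.3, 6.74, tolerance = 0.005)
  expect_equal(m$relative_sec, 100 * m$sec / 611.3)

  expect_error(calibration_metrics(c(1, 2, 3), c(5, 5, 5)),
               class = "xrfnet_degenerate_error")
  expect_error(calibration_metrics(c(1, 2), c(1, 2)),
               class = "xrfnet_validation_error")
})

# builds a vector with an exact mean and exact sample SD
with_moments <- function(n, mean, sd) {
  x <- scale(seq_len(n))[, 1]
  mean + sd * x / sd(x)
}

test_that("detection limits reproduce the published scenario arithmetic", {
  # scenario 1, As: mean 113.69, s0 9.39, n = 3
  p1 <- with_moments(10, 113.69, 9.39)
  l1 <- detection_limits(p1, n = 3, actual = 128.97, element = "As")
  expect_equal(l1$s0, 9.39, tolerance = 1e-9)
  expect_equal(l1$lod, 16.26, tolerance = 0.01)
  expect_equal(l1$loq, 54.20, tolerance = 0.05)
  expect_equal(l1$bias_abs, -15.28, tolerance = 1e-9) # formula, not the printed -15.38
  expect_equal(l1$bias_pct, -11.85, tolerance = 0.01)

  # scenario 2, Pb: mean 134.87, s0 14.94
  p2 <- with_moments(10, 134.87, 14.94)
  l2 <- detection_limits(p2, n = 3, actual = 208.95, element = "Pb")
  expect_equal(l2$bias_abs, -74.08, tolerance = 1e-9)
  expect_equal(l2$lod, 25.87, tolerance = 0.05)
  expect_equal(l2$loq, 86.23, tolerance = 0.05)

  # identical predictions: zero spread, zero limits
  l0 <- detection_limits(rep(120, 10), n = 3, actual = 128.97)
  expect_equal(l0$s0, 0)
  expect_equal(l0$lod, 0)
  expect_equal(l0$loq, 0)

  expect_error(detection_limits(p1, n = 0, actual = 1),
               class = "xrfnet_domain_error")
})

test_that("LOQ/LOD keep the exact kQ/3 ratio and scale equivariantly", {
  for (i in 1:20) {
    set.seed(100 + i)
    p <- rnorm(10, 150, 12)
    l <- detection_limits(p, n = 3, actual = 150)
    expect_equal(l$loq / l$lod, 10 / 3, tolerance = 1e-12)

    c0 <- 1 + runif(1, 0, 4)
    ls <- detection_limits(c0 * p, n = 3, actual = c0 * 150)
    expect_equal(ls$s0, c0 * l$s0, tolerance = 1e-10)
    expect_equal(ls$lod, c0 * l$lod, tolerance = 1e-10)
    expect_equal(ls$loq, c0 * l$loq, tolerance = 1e-10)
    expect_equal(ls$bias_abs, c0 * l$bias_abs, tolerance = 1e-8)
    expect_equal(ls$bias_pct, l$bias_pct, tolerance = 1e-8)
  }
})

test_that("the blank-based reference-method LOQ follows 10 sigma over slope", {
  expect_equal(icp_loq(0.1, 1), 1.0)
  expect_equal(icp_loq(0, 2), 0)
  expect_equal(icp_loq(0.659, 1), 6.59) # the reported Pb LOQ magnitude
  expect_error(icp_loq(0.1, 0), class = "xrfnet_domain_error")
})

test_that("agreement records implement the +/-20% protocol", {
  crm <- assess_agreement(209.50, 260, sample = "CRM", element = "As")
  expect_equal(crm$error_pct, 100 * (209.50 - 260) / 260, tolerance = 1e-12)
  expect_equal(crm$error_pct, -19.42, tolerance = 0.01)
  expect_true(crm$agrees)

  # +30.33% on 56.84 ug/kg is only +17.24 ug/kg absolute
  wafer <- assess_agreement(56.84 * 1.3033, 56.84)
  expect_equal(wafer$error_abs, 17.24, tolerance = 0.01)
  expect_false(wafer$agrees)

  exact <- assess_agreement(150, 150)
  expect_equal(exact$error_pct, 0)
  expect_true(exact$agrees)

  below <- assess_agreement(80, 5, loq = 54.2)
  expect_false(below$quantifiable)
  expect_true(is.na(below$agrees))
  expect_equal(below$error_abs, 75)

  zero <- assess_agreement(3, 0)
  expect_true(is.na(zero$error_pct))
  expect_equal(zero$error_abs, 3)
})

test_that("category summaries follow the published table conventions", {
  rec <- function(pred, actual, cat, el = "As", loq = 0) {
    dplyr::mutate(assess_agreement(pred, actual, loq = loq, element = el),
                  category = cat)
  }
  one <- category_summary(rec(260 * (1 - 0.1943), 260, "crm"))
  expect_equal(one$mean_abs_error, 19.43, tolerance = 1e-9)
  expect_equal(one$median_abs_error, one$mean_abs_error) # n = 1

  three <- category_summary(dplyr::bind_rows(
    rec(110, 100, "c"), rec(120, 100, "c"), rec(130, 100, "c")
  ))
  expect_equal(three$mean_abs_error, 20)
  expect_equal(three$median_abs_error, 20)

  even <- category_summary(dplyr::bind_rows(
    rec(110, 100, "c"), rec(90, 100, "c"),
    rec(125, 100, "c"), rec(130, 100, "c")
  ))
  expect_equal(even$median_abs_error, (10 + 25) / 2)

  # a non-quantifiable record switches the cell to absolute ug/kg errors
  mixed <- category_summary(dplyr::bind_rows(
    rec(84, 3, "c", el = "Pb", loq = 86.23),
    rec(90, 5, "c", el = "Pb", loq = 86.23)
  ))
  expect_equal(mixed$unit, "ug/kg")
  expect_equal(mixed$mean_abs_error, mean(c(81, 85)))

  expect_error(category_summary(rec(1, 1, "c")[0, ]),
               class = "xrfnet_validation_error")
})
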