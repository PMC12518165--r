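test_that("predictions from published coefficients reproduce reported means", {
  fit <- cqt_fit_from_coefficients(-2.7863, 0.0054)
  expect_equal(round(predict(fit, 86)$mean_ms, 1), -2.3)
  expect_equal(round(predict(fit, 180.7)$mean_ms, 1), -1.8)
  expect_equal(predict(fit, 0)$mean_ms, -2.7863)      # conc 0 -> intercept
  moxi <- cqt_fit_from_coefficients(2.5997, 0.0044)
  expect_equal(round(predict(moxi, 2367.1)$mean_ms, 1), 13.0)
  expect_error(predict(fit, -5), "non-negative")
})

test_that("prediction mean is affine in concentration and CI width grows past the variance minimum", {
  rows <- simulated_rows(seed = 10)
  fit <- fit_cqtc(rows)
  conc <- seq(0, 600, by = 10)
  p <- predict(fit, conc)
  # affine: second differences vanish
  expect_equal(max(abs(diff(diff(p$mean_ms)))), 0, tolerance = 1e-10)
  # half-width non-decreasing beyond the minimising concentration
  v <- vcov(fit)
  c_min <- -v[1, 2] / v[2, 2]
  hw <- (p$ci_upper_ms - p$ci_lower_ms) / 2
  beyond <- conc >= max(c_min, 0)
  expect_true(all(diff(hw[beyond]) >= -1e-12))
  expect_true(all(p$ci_lower_ms <= p$mean_ms & p$mean_ms <= p$ci_upper_ms))
})

test_that("concentration of interest multiplies and rounds as reported", {
  expect_equal(as.numeric(concentration_of_interest(43.1, 2)), 86)
  expect_equal(attr(concentration_of_interest(43.1, 2), "exact"), 86.2)
  expect_equal(as.numeric(concentration_of_interest(43.1, 1)), 43)
  expect_equal(as.numeric(concentration_of_interest(50, 2)), 100)
  expect_error(concentration_of_interest(-1), "positive")
})

test_that("the 10-ms exclusion verdict uses a strict upper-bound inequality", {
  pass <- cqt_prediction(86, -2.3, -3.7, -0.9)
  expect_true(assess_no_prolongation(pass)$passed)
  at_bound <- cqt_prediction(86, 5, 0, 10.0)
  expect_false(assess_no_prolongation(at_bound)$passed)
  just_under <- cqt_prediction(86, 5, 0, 9.99)
  expect_true(assess_no_prolongation(just_under)$passed)
})

test_that("assay sensitivity requires the lower bound strictly above 5 ms", {
  pass <- cqt_prediction(2367.1, 13.0, 8.8, 17.2)
  expect_true(assess_assay_sensitivity(pass)$passed)
  expect_false(assess_assay_sensitivity(cqt_prediction(2367.1, 7, 5.0, 9))$passed)
  expect_false(assess_assay_sensitivity(cqt_prediction(2367.1, 6, 4.0, 8))$passed)
})

test_that("verdicts from a fitted model agree with its predicted bounds", {
  rows <- simulated_rows(seed = 11)
  fit <- fit_cqtc(rows)
  p <- predict(fit, 86)
  v <- assess_no_prolongation(fit, 86)
  expect_equal(v$bound_ms, p$ci_upper_ms)
  expect_equal(v$passed, p$ci_upper_ms < 10)
})

test_that("paired-t exclusion power matches a Monte-Carlo oracle", {
  # degenerate limits
  expect_equal(power_paired_exclusion(24, 0, true_effect_ms = 0), 1)
  expect_equal(power_paired_exclusion(24, 8, true_effect_ms = 10,
                                      margin_ms = 10), 0.05,
               tolerance = 1e-10)
  # Monte-Carlo oracle: 1e5 simulated paired studies
  set.seed(123)
  n <- 24
  sd <- 8
  reps <- 1e5
  x <- matrix(rnorm(reps * n, 0, sd), reps, n)
  mean_x <- rowMeans(x)
  sd_x <- sqrt((rowSums(x^2) - n * mean_x^2) / (n - 1))
  upper <- mean_x + qt(0.95, n - 1) * sd_x / sqrt(n)
  mc <- mean(upper < 10)
  expect_equal(power_paired_exclusion(24, 8), mc, tolerance = 5e-3)
  expect_gt(power_paired_exclusion(24, 8), 0.91)
})
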