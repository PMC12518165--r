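test_that("heart-rate check passes under 10 bpm and fails at the strict boundary", {
  d <- data.frame(time_h = rep(c(1, 2, 4), each = 2),
                  ddhr_bpm = c(3, 3, -2, -2, 4, 4))
  expect_true(check_hr_effect(d)$passed)
  d2 <- data.frame(time_h = rep(c(1, 2), each = 2),
                   ddhr_bpm = c(3, 3, 12, 12))
  chk <- check_hr_effect(d2)
  expect_false(chk$passed)
  expect_equal(chk$failed_times, 2)
  # exactly 10 bpm fails (strict)
  d3 <- data.frame(time_h = 1, ddhr_bpm = 10)
  expect_false(check_hr_effect(d3)$passed)
  # verdict invariant to timepoint ordering
  expect_equal(check_hr_effect(d2[sample(nrow(d2)), ])$passed, chk$passed)
})

test_that("hysteresis check compares peak times with earliest-maximum ties", {
  t <- c(0.5, 1, 2, 4, 6, 8)
  conc <- c(10, 50, 100, 80, 50, 30)
  expect_false(check_hysteresis(t, conc, c(0, 1, 5, 3, 2, 1))$flagged)
  chk <- check_hysteresis(t, conc, c(0, 1, 2, 3, 5, 2), lag_tolerance_h = 1)
  expect_true(chk$flagged)
  expect_equal(chk$lag_h, 4)
  # flat effect course: earliest maximum
  flat <- check_hysteresis(t, conc, rep(1, 6))
  expect_equal(flat$t_peak_ddqtcf_h, 0.5)
  expect_error(check_hysteresis(1:3, 1:3, 1:3), ">= 4")
})

test_that("linearity check is silent on a line and flags dominant curvature", {
  set.seed(42)
  x <- runif(60, 0, 400)
  chk_lin <- check_linearity(x, 2 + 0.01 * x)
  expect_false(chk_lin$flagged)
  expect_lt(chk_lin$max_discrepancy_ms, 1e-6)
  # strong quadratic: curvature dominates the residual SD rule
  y <- ((x - mean(x)) / 100)^2 * 10
  chk_quad <- check_linearity(x, y)
  expect_true(chk_quad$flagged)
  # span 1.0 on linear data: still exact
  expect_lt(check_linearity(x, 1 + 0.02 * x, span = 1)$max_discrepancy_ms,
            1e-6)
})

test_that("linearity flag decision is invariant to concentration rescaling", {
  set.seed(43)
  x <- runif(50, 0, 500)
  y <- ((x - mean(x)) / 120)^2 * 8 + rnorm(50, 0, 0.5)
  a <- check_linearity(x, y)
  b <- check_linearity(x / 1000, y)       # ng/mL -> ug/mL
  expect_equal(a$flagged, b$flagged)
  expect_equal(a$max_discrepancy_ms, b$max_discrepancy_ms,
               tolerance = 1e-6)
  expect_error(check_linearity(1:10, 1:10), ">= 20")
})

test_that("decile summary splits positive-concentration rows near-equally", {
  x100 <- seq_len(100)
  d100 <- decile_summary(x100, rep(1, 100))
  expect_equal(d100$n, rep(10, 10))
  x103 <- seq_len(103)
  d103 <- decile_summary(x103, rnorm(103))
  expect_equal(d103$n, c(11, 11, 11, rep(10, 7)))
  expect_equal(sum(d103$n), 103)
  expect_lte(max(d103$n) - min(d103$n), 1)
  # constant response: every group mean equal with zero-width interval
  dd <- decile_summary(x100, rep(7, 100))
  expect_equal(dd$ddqtcf_mean, rep(7, 10))
  expect_equal(dd$ci_upper - dd$ci_lower, rep(0, 10))
  # zero-concentration rows are excluded from the partition
  dmix <- decile_summary(c(rep(0, 5), x100), c(rep(99, 5), rep(1, 100)))
  expect_equal(sum(dmix$n), 100)
  expect_error(decile_summary(1:5, 1:5), ">= 10")
})

test_that("covariate impact check flags a shifted group and not identical groups", {
  d <- expand.grid(subject = 1:8, time_h = c(1, 2, 4),
                   group = c("challenge", "control"))
  set.seed(9)
  d$dqtcf_ms <- rnorm(nrow(d), 0, 2)
  chk <- check_covariate_impact(d, "group")
  expect_false(is.na(chk$max_group_difference_ms))
  d$dqtcf_ms[d$group == "challenge"] <- d$dqtcf_ms[d$group == "challenge"] + 10
  expect_true(check_covariate_impact(d, "group")$flagged)
})

test_that("the consolidated diagnostic report runs on simulated study rows", {
  # a clear direct-effect signal: the gates should all stay quiet
  cfg <- tqt_config(qtc = list(slope_ms_per_ng_ml = 0.02,
                               residual_sd_ms = 1.5))
  study <- simulate_study(cfg, seed = 31)
  rows <- derive_tqt(study)
  rep <- cqt_diagnostics(rows)
  expect_s3_class(rep, "cqt_diagnostics")
  expect_true(rep$hr$passed)                # no HR effect simulated
  expect_false(rep$hysteresis$flagged)      # direct-effect generator
  expect_false(rep$linearity$flagged)       # linear generator
  expect_equal(sum(rep$deciles$n), sum(rows$conc > 0))
})
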