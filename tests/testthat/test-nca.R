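test_that("the worked three-point profile is reproduced exactly", {
  r <- nca_profile(c(0, 1, 2), c(0, 10, 5))
  expect_equal(r$cmax, 10)
  expect_equal(r$tmax_h, 1)
  expect_equal(r$auc_last, 5 + 5 / log(2), tolerance = 1e-12)
  expect_equal(r$lambda_z, log(2), tolerance = 1e-12)
  expect_equal(r$auc_inf, 5 + 10 / log(2), tolerance = 1e-12)
  expect_equal(r$t_half_h, 1, tolerance = 1e-12)
  expect_equal(r$extrapolated_fraction,
               (5 / log(2)) / (5 + 10 / log(2)), tolerance = 1e-12)
})

test_that("a flat profile leaves the terminal phase undefined with a reason", {
  r <- nca_profile(c(0, 1, 2, 4), c(5, 5, 5, 5))
  expect_true(is.na(r$auc_inf))
  expect_true(is.na(r$t_half_h))
  expect_match(r$lambda_reason, "non-negative|unfit")
  expect_error(nca_profile(c(0, 1, 2), c(0, 0, 0)), "positive")
  expect_error(nca_profile(c(0, 1, 1), c(0, 1, 2)), "increasing")
})

test_that("NCA is homogeneous in concentration and equivariant in time units", {
  t <- c(0, 0.5, 1, 2, 4, 8, 12, 24, 48)
  c1 <- simulate_pk_profile(tqt_config()$pk, 32, t)
  r1 <- nca_profile(t, c1)
  r2 <- nca_profile(t, 2 * c1)
  expect_equal(r2$cmax, 2 * r1$cmax)
  expect_equal(r2$auc_last, 2 * r1$auc_last, tolerance = 1e-12)
  expect_equal(r2$auc_inf, 2 * r1$auc_inf, tolerance = 1e-10)
  expect_equal(r2$tmax_h, r1$tmax_h)
  expect_equal(r2$lambda_z, r1$lambda_z, tolerance = 1e-12)
  # minutes instead of hours: lambda_z scales by 60
  r3 <- nca_profile(t * 60, c1)
  expect_equal(r3$lambda_z * 60, r1$lambda_z, tolerance = 1e-9)
  expect_equal(r3$auc_last / 60, r1$auc_last, tolerance = 1e-9)
})

test_that("linear-up/log-down equals the linear trapezoid on a non-decreasing profile", {
  t <- c(0, 1, 2, 3, 4)
  cc <- c(0, 2, 5, 5, 9)
  r <- nca_profile(t, cc)
  lin <- sum(diff(t) * (head(cc, -1) + tail(cc, -1)) / 2)
  expect_equal(r$auc_last, lin, tolerance = 1e-12)
})

test_that("dense noise-free sampling recovers the true terminal rate constant", {
  pk <- tqt_config()$pk
  k10 <- pk$cl_f / pk$v1_l
  k12 <- pk$q_l_h / pk$v1_l
  k21 <- pk$q_l_h / pk$v2_l
  s <- k10 + k12 + k21
  beta_true <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
  t_half <- log(2) / beta_true
  # 1-minute sampling across five terminal half-lives
  t <- c(seq(0, 24, by = 1), seq(25, 24 + 5 * t_half, by = 1 / 60))
  cc <- simulate_pk_profile(pk, 32, t)
  r <- nca_profile(t, cc)
  expect_equal(r$lambda_z, beta_true, tolerance = 0.05)
})

test_that("geometric summaries match the closed form", {
  g <- geometric_summary(c(100, 400))
  expect_equal(g$gmean, 200)
  s <- log(4) / sqrt(2)
  expect_equal(g$gcv_percent, 100 * sqrt(exp(s^2) - 1), tolerance = 1e-12)
  expect_equal(round(g$gcv_percent, 1), 127.0)
  expect_equal(geometric_summary(c(5, 5, 5))$gcv_percent, 0)
  expect_error(geometric_summary(c(1, -1)), "positive")
  expect_error(geometric_summary(3), ">= 2")
})

test_that("dose proportionality normalises by dose and flags outside the band", {
  exact <- dose_proportionality(c(16, 32), c(100, 200))
  expect_equal(exact$cmax_ratio, c(1, 1))
  expect_false(any(exact$cmax_flagged))
  rep <- dose_proportionality(c(16, 32), c(180.7, 412.1))
  expect_equal(rep$cmax_ratio[2], (412.1 / 2) / 180.7, tolerance = 1e-12)
  expect_equal(round(rep$cmax_ratio[2], 3), 1.140)
  expect_false(any(rep$cmax_flagged))
  high <- dose_proportionality(c(16, 32), c(100, 260))
  expect_true(high$cmax_flagged[2])
  expect_error(dose_proportionality(16, 100), ">= 2")
})

test_that("the accumulation ratio follows the half-life/interval closed form", {
  expect_equal(accumulation_ratio(29, 24), 1 / (1 - 2^(-24 / 29)))
  expect_equal(round(accumulation_ratio(29, 24), 1), 2.3)
  # a short half-life accumulates negligibly
  expect_equal(accumulation_ratio(4, 24), 1, tolerance = 0.02)
  expect_error(accumulation_ratio(-1), "positive")
})
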