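test_that("the same seed reproduces a study bit-identically", {
  a <- simulate_study(tqt_config(), seed = 99)
  b <- simulate_study(tqt_config(), seed = 99)
  expect_identical(a$ecg, b$ecg)
  expect_identical(a$pk, b$pk)
  expect_identical(a$truth, b$truth)
  c <- simulate_study(tqt_config(), seed = 100)
  expect_false(identical(a$ecg, c$ecg))
})

test_that("the crossover design is balanced: 7 subjects per sequence, Latin square", {
  study <- simulate_study(tqt_config(), seed = 1)
  expect_equal(as.integer(table(study$truth$sequence)), rep(7L, 4))
  sq <- study$config$sequences
  expect_true(all(apply(sq, 1, anyDuplicated) == 0))
  expect_true(all(apply(sq, 2, anyDuplicated) == 0))
  # every subject sees each treatment exactly once
  trt_count <- table(study$ecg$subject_id, study$ecg$treatment)
  expect_true(all(trt_count == length(unique(study$ecg$time_h))))
})

test_that("concentration is zero at dosing time and the one-compartment limit holds", {
  pk <- tqt_config()$pk
  expect_equal(simulate_pk_profile(pk, 32, 0), 0)
  expect_equal(simulate_pk_profile(pk, 32, -1), 0)
  # q = 0 reduces to the closed one-compartment form
  pk1 <- list(ka = 1.2, cl_f = 3.2, v1_l = 55, q_l_h = 0)
  t <- c(0.5, 1, 2, 6, 24)
  k <- pk1$cl_f / pk1$v1_l
  expected <- 1000 * 32 / pk1$v1_l * pk1$ka / (pk1$ka - k) *
    (exp(-k * t) - exp(-pk1$ka * t))
  expect_equal(simulate_pk_profile(pk1, 32, t), expected,
               tolerance = 1e-12)
  # two-compartment with negligible peripheral exchange approaches it
  pk2 <- list(ka = 1.2, cl_f = 3.2, v1_l = 55, v2_l = 60, q_l_h = 1e-8)
  expect_equal(simulate_pk_profile(pk2, 32, t), expected,
               tolerance = 1e-4)
})

test_that("reference PK emulates the target exposure range", {
  study <- simulate_study(tqt_config(), seed = 5)
  nca <- nca_by_subject(study$pk, "drug")
  gmean32 <- exp(mean(log(nca$cmax[nca$treatment == "active_32mg"])))
  expect_gt(gmean32, 260)
  expect_lt(gmean32, 617)
  # tmax within 0.5-4 h for at least 95% of profiles
  expect_gte(mean(nca$tmax_h >= 0.5 & nca$tmax_h <= 4), 0.95)
  # biphasic: terminal slope much shallower than the initial decline
  prof <- simulate_pk_profile(study$config$pk, 32, c(4, 8, 24, 48))
  early <- log(prof[1] / prof[2]) / 4
  late <- log(prof[3] / prof[4]) / 24
  expect_gt(early / late, 2)
})

test_that("zero-noise generation is exact through the full derivation chain", {
  # zero noise, zero slope, with diurnal rhythm: everything cancels
  cfg0 <- tqt_config(qtc = list(slope_ms_per_ng_ml = 0, residual_sd_ms = 0,
                                omega = matrix(0, 2, 2)))
  s0 <- simulate_study(cfg0, seed = 3)
  rows0 <- derive_tqt(s0)
  expect_lt(max(abs(rows0$ddqtcf_ms)), 1e-9)
  # zero noise, nonzero slope: ddqtcf == slope * conc exactly
  cfg1 <- tqt_config(qtc = list(slope_ms_per_ng_ml = 0.01,
                                residual_sd_ms = 0,
                                omega = matrix(0, 2, 2)))
  s1 <- simulate_study(cfg1, seed = 3)
  rows1 <- derive_tqt(s1)
  expect_equal(rows1$ddqtcf_ms, 0.01 * rows1$conc, tolerance = 1e-9)
})

test_that("re-derivation recovers the generated QTcF through the Fridericia inverse", {
  study <- simulate_study(tqt_config(), seed = 12)
  d <- derive_qtcf(study$ecg)
  # QT was back-computed from QTcF and RR, so QTcF round-trips exactly
  expect_equal(d$qtcf_ms, d$qt_ms / (d$rr_ms / 1000)^(1 / 3),
               tolerance = 1e-12)
  expect_true(all(d$qt_ms < d$rr_ms))
})

test_that("MAD superposition accumulates according to the terminal half-life", {
  cfg <- mad_config(qtc = list(residual_sd_ms = 0,
                               omega = matrix(0, 2, 2)))
  study <- simulate_study(cfg, seed = 8)
  pk <- study$pk
  one <- pk[pk$subject_id == pk$subject_id[1], ]
  # trough accumulation: 24 h after the first dose vs day-10 pre-dose
  trough1 <- one$conc[one$day == 1 & one$time_h == 24]
  trough10 <- one$conc[one$day == 10 & one$time_h == 0]
  r_obs <- trough10 / trough1
  expect_gt(r_obs, 1.5)
  expect_lt(r_obs, 4)
  # day-10 pre-dose trough is positive (steady state), day-1 pre-dose zero
  expect_equal(one$conc[one$day == 1 & one$time_h == 0], 0)
  expect_gt(one$conc[one$day == 10 & one$time_h == 0], 0)
})

test_that("the MAD cohorts reproduce the 3:1 parallel randomisation", {
  study <- simulate_study(mad_config(), seed = 2)
  expect_equal(nrow(study$truth), 56)
  expect_equal(sum(study$truth$treatment == "placebo"), 14)
  expect_equal(sum(study$truth$treatment != "placebo"), 42)
  expect_equal(length(unique(study$truth$cohort)), 5)
})

test_that("the fitted slope is centred on the generating slope over replicates", {
  slopes <- vapply(1:12, function(r) {
    st <- simulate_study(tqt_config(), seed = 5000 + r)
    rw <- derive_tqt(st)
    coef(suppressWarnings(fit_cqtc(rw)))[["slope"]]
  }, 0)
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.0054), 4 * mc_se)
})
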