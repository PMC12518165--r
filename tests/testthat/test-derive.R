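test_that("heart rate and Fridericia correction give exact values", {
  expect_equal(heart_rate(c(1000, 800, 500)), c(60, 75, 120))
  expect_error(heart_rate(0), "positive")
  expect_equal(fridericia(400, 1000), 400)           # RR = 1 s identity
  expect_equal(fridericia(350, 729), 350 / 0.9)      # perfect-cube RR
  expect_equal(fridericia(400, 800), 400 / 0.8^(1 / 3), tolerance = 1e-12)
  expect_error(fridericia(-1, 800), "positive")
  expect_error(fridericia(400, 0), "positive")
})

test_that("Fridericia is decreasing in RR and degree-1 homogeneous in QT", {
  rr <- seq(400, 1400, by = 50)
  q <- fridericia(400, rr)
  expect_true(all(diff(q) < 0))
  for (k in c(0.5, 2, 3.7)) {
    expect_equal(fridericia(k * 400, rr), k * q, tolerance = 1e-12)
  }
})

test_that("baseline adjustment uses the mean of pre-dose replicates", {
  ecg <- data.frame(subject_id = "S1", treatment = "active", period = 1,
                    day = 1, time_h = c(-0.3, -0.1, 2),
                    qt_ms = c(398, 402, 410), rr_ms = 1000)
  adj <- baseline_adjust(derive_qtcf(ecg))
  expect_equal(unique(adj$baseline_qtcf_ms), 400)
  expect_equal(adj$dqtcf_ms[adj$time_h == 2], 10)
})

test_that("a subject x period without a pre-dose record is excluded", {
  ecg <- data.frame(subject_id = c("S1", "S1", "S2"),
                    treatment = "active", period = 1, day = 1,
                    time_h = c(-0.25, 2, 2),
                    qt_ms = c(400, 400, 405), rr_ms = 1000)
  expect_warning(adj <- baseline_adjust(derive_qtcf(ecg)), "no pre-dose")
  expect_false("S2" %in% adj$subject_id)
  expect_equal(attr(adj, "n_excluded"), 1)
  expect_equal(adj$dqtcf_ms[adj$time_h == 2], 0)   # single baseline identity
})

test_that("crossover placebo correction is a time-matched difference", {
  ecg <- tiny_crossover_ecg()
  adj <- baseline_adjust(derive_qtcf(ecg))
  rows <- placebo_correct_crossover(adj)
  post <- rows[rows$time_h > 0, ]
  # active adds 5*t ms over an identical placebo course
  expect_equal(post$ddqtcf_ms, 5 * post$time_h, tolerance = 1e-9)
  expect_equal(attr(rows, "dropped"), 0)
})

test_that("identical active and placebo arms give ddQTcF == 0 and rows are accounted", {
  ecg <- tiny_crossover_ecg()
  ecg$qt_ms[ecg$treatment == "active"] <-
    ecg$qt_ms[ecg$treatment == "placebo"]
  adj <- baseline_adjust(derive_qtcf(ecg))
  rows <- placebo_correct_crossover(adj)
  expect_equal(rows$ddqtcf_ms, rep(0, nrow(rows)), tolerance = 1e-12)
  n_active <- sum(adj$treatment != "placebo")
  expect_equal(nrow(rows) + attr(rows, "dropped"), n_active)
})

test_that("active rows without a time-matched placebo record are dropped and counted", {
  ecg <- tiny_crossover_ecg()
  ecg <- ecg[!(ecg$treatment == "placebo" & ecg$time_h == 2), ]
  adj <- baseline_adjust(derive_qtcf(ecg))
  rows <- placebo_correct_crossover(adj)
  expect_equal(attr(rows, "dropped"), 2)   # t = 2 h for both subjects
  expect_false(any(rows$time_h == 2))
  n_active <- sum(adj$treatment != "placebo")
  expect_equal(nrow(rows) + attr(rows, "dropped"), n_active)
})

test_that("parallel correction subtracts the pooled placebo mean", {
  ecg <- data.frame(
    subject_id = c("A1", "P1", "P2"),
    treatment = c("active", "placebo", "placebo"),
    period = 1, day = 1)
  ecg <- merge(ecg, data.frame(time_h = c(-0.25, 2)))
  ecg$rr_ms <- 1000
  ecg$qt_ms <- 400
  # post-dose changes: active +4; placebo +1 and +3 (mean 2)
  ecg$qt_ms[ecg$time_h > 0] <- 400 + c(4, 1, 3)[
    match(ecg$subject_id[ecg$time_h > 0], c("A1", "P1", "P2"))]
  adj <- baseline_adjust(derive_qtcf(ecg))
  rows <- placebo_correct_parallel(adj)
  expect_equal(rows$ddqtcf_ms[rows$time_h == 2], 2)
  # single placebo subject with zero change: ddqtcf = active dqtcf
  ecg2 <- ecg[ecg$subject_id != "P2", ]
  ecg2$qt_ms[ecg2$subject_id == "P1" & ecg2$time_h > 0] <- 400
  rows2 <- placebo_correct_parallel(baseline_adjust(derive_qtcf(ecg2)))
  expect_equal(rows2$ddqtcf_ms[rows2$time_h == 2], 4)
  # empty placebo arm is a design error
  ecg3 <- ecg[ecg$treatment == "active", ]
  expect_error(placebo_correct_parallel(baseline_adjust(derive_qtcf(ecg3))),
               "placebo")
})

test_that("concentration pairing is exact on nominal time with pre-dose zero", {
  ecg <- tiny_crossover_ecg()
  adj <- baseline_adjust(derive_qtcf(ecg))
  rows <- placebo_correct_crossover(adj)
  paired <- pair_concentration(rows, tiny_crossover_pk())
  expect_equal(paired$conc[paired$time_h == 2], rep(200, 2))
  expect_equal(paired$conc[paired$time_h <= 0], rep(0, 2))
  # a row at a time with no PK sample is dropped and counted
  pk_sparse <- tiny_crossover_pk()
  pk_sparse <- pk_sparse[pk_sparse$time_h != 2, ]
  expect_warning(p2 <- pair_concentration(rows, pk_sparse), "dropped")
  expect_equal(attr(p2, "dropped"), 2)
  expect_equal(nrow(p2) + attr(p2, "dropped"), nrow(rows))
})
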