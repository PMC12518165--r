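# Shared fixture builders. Everything is generated in code; no stored
# data files are needed.

# A tiny hand-built crossover ECG frame: 2 subjects, active + placebo,
# one pre-dose and two post-dose records each, no noise.
tiny_crossover_ecg <- function() {
  grid <- expand.grid(subject_id = c("S1", "S2"),
                      treatment = c("active", "placebo"),
                      time_h = c(-0.25, 1, 2),
                      stringsAsFactors = FALSE)
  grid$period <- ifelse(grid$treatment == "active", 1, 2)
  grid$day <- 1
  grid$rr_ms <- 1000                       # QTcF == QT
  base <- ifelse(grid$subject_id == "S1", 400, 410)
  drug <- ifelse(grid$treatment == "active" & grid$time_h > 0,
                 5 * grid$time_h, 0)       # +5 ms at 1 h, +10 ms at 2 h
  grid$qt_ms <- base + drug
  grid[order(grid$subject_id, grid$treatment, grid$time_h), ]
}

tiny_crossover_pk <- function() {
  grid <- expand.grid(subject_id = c("S1", "S2"),
                      time_h = c(0, 1, 2),
                      stringsAsFactors = FALSE)
  grid$treatment <- "active"
  grid$period <- 1
  grid$analyte <- "drug"
  grid$conc <- ifelse(grid$time_h == 0, 0, 100 * grid$time_h)
  grid
}

# Model rows on an exact line ddqtcf = a + b*conc, equal baselines.
exact_linear_rows <- function(a = 1, b = 0.01, n_subj = 6) {
  rows <- expand.grid(subject_id = sprintf("S%d", seq_len(n_subj)),
                      conc = c(0, 50, 100, 200, 400),
                      stringsAsFactors = FALSE)
  rows$baseline_qtcf_ms <- 400
  rows$ddqtcf_ms <- a + b * rows$conc
  rows
}

# Noisy mixed-model rows with known generating values, deterministic.
simulated_rows <- function(seed = 1, n_subj = 20, theta0 = -2,
                           slope = 0.005, theta2 = -0.3,
                           sd_int = 2, sd_slope = 0.0015, sigma = 5) {
  set.seed(seed)
  conc_grid <- c(0, 25, 50, 100, 200, 350, 500)
  rows <- expand.grid(subject_id = sprintf("S%02d", seq_len(n_subj)),
                      conc = conc_grid, stringsAsFactors = FALSE)
  base <- stats::rnorm(n_subj, 410, 12)
  names(base) <- sprintf("S%02d", seq_len(n_subj))
  eta0 <- stats::rnorm(n_subj, 0, sd_int)
  eta1 <- stats::rnorm(n_subj, 0, sd_slope)
  names(eta0) <- names(eta1) <- names(base)
  rows$baseline_qtcf_ms <- base[rows$subject_id]
  rows$ddqtcf_ms <- theta0 + eta0[rows$subject_id] +
    (slope + eta1[rows$subject_id]) * rows$conc +
    theta2 * (rows$baseline_qtcf_ms - mean(base)) +
    stats::rnorm(nrow(rows), 0, sigma)
  rows
}

# Independent dense-matrix evaluation of the restricted log-likelihood
# of the C-QTc model at given (omega, sigma2) -- used as an oracle
# against the package's profiled criterion.
dense_reml_loglik <- function(omega, sigma2, rows, baseline_centre) {
  subj <- factor(rows$subject_id)
  X <- cbind(1, rows$conc, rows$baseline_qtcf_ms - baseline_centre)
  y <- rows$ddqtcf_ms
  n <- length(y)
  p <- ncol(X)
  V <- matrix(0, n, n)
  for (s in levels(subj)) {
    ii <- which(subj == s)
    Z <- cbind(1, rows$conc[ii])
    V[ii, ii] <- Z %*% omega %*% t(Z)
  }
  diag(V) <- diag(V) + sigma2
  cv <- chol(V)
  ldV <- 2 * sum(log(diag(cv)))
  Vi <- chol2inv(cv)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  q <- drop(t(r) %*% Vi %*% r)
  -0.5 * (ldV + log(det(XtVX)) + q + (n - p) * log(2 * pi))
}

active_labels <- c("active_16mg", "active_32mg")

derive_tqt <- function(study) {
  suppressWarnings(derive_cqt_rows(study$ecg, study$pk,
                                   design = "crossover",
                                   active = active_labels))
}
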