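test_that("exact linear data are recovered with vanishing variance components", {
  rows <- exact_linear_rows(a = 1, b = 0.01)
  fit <- suppressWarnings(fit_cqtc(rows, baseline = FALSE))
  expect_equal(unname(coef(fit)[1]), 1, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[2]), 0.01, tolerance = 1e-8)
  expect_lt(fit$sigma2, 1e-10)
  expect_lt(max(abs(fit$omega)), 1e-8)
})

test_that("balanced one-way REML matches the closed-form ANOVA estimators", {
  set.seed(5)
  m <- 6
  k <- 4
  b <- rnorm(m, 0, 3)
  y <- 10 + rep(b, each = k) + rnorm(m * k, 0, 2)
  subj <- rep(seq_len(m), each = k)
  eng <- lmm_reml(y, matrix(1, m * k, 1), subj, random = "intercept")
  mse <- sum((y - ave(y, subj))^2) / (m * (k - 1))
  msa <- k * var(tapply(y, subj, mean))
  expect_equal(eng$sigma2, mse, tolerance = 1e-6)
  expect_equal(eng$omega[1, 1], (msa - mse) / k, tolerance = 1e-6)
})

test_that("Omega constrained to zero reproduces ordinary least squares", {
  rows <- simulated_rows(seed = 2)
  fit <- fit_cqtc(rows, random = "none")
  bc <- rows$baseline_qtcf_ms - fit$baseline_centre
  ols <- lm(ddqtcf_ms ~ conc + bc, data = cbind(rows, bc = bc))
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fit$sigma2, sigma(ols)^2, tolerance = 1e-10)
  expect_equal(unname(sqrt(diag(vcov(fit)))),
               unname(sqrt(diag(vcov(ols)))), tolerance = 1e-8)
})

test_that("full model agrees with an independent REML implementation", {
  skip_if_not_installed("lme4")
  rows <- simulated_rows(seed = 3)
  fit <- fit_cqtc(rows)
  d <- rows
  d$bc <- d$baseline_qtcf_ms - fit$baseline_centre
  d$conc_s <- d$conc / sd(d$conc)            # conditioning for lme4
  lf <- lme4::lmer(ddqtcf_ms ~ conc_s + bc + (1 + conc_s | subject_id),
                   data = d, REML = TRUE)
  s <- sd(d$conc)
  fe <- lme4::fixef(lf)
  expect_equal(unname(coef(fit)),
               unname(c(fe[1], fe[2] / s, fe[3])), tolerance = 1e-4)
  expect_equal(fit$logLik, as.numeric(logLik(lf)) - log(s),
               tolerance = 1e-6)
  vc <- lme4::VarCorr(lf)$subject_id[1:2, 1:2]
  vc <- diag(c(1, 1 / s)) %*% vc %*% diag(c(1, 1 / s))
  expect_equal(unname(fit$omega), unname(vc), tolerance = 5e-2)
  expect_equal(fit$sigma2, sigma(lf)^2, tolerance = 1e-3)
})

test_that("the attained criterion is a local optimum of the restricted likelihood", {
  rows <- simulated_rows(seed = 4, n_subj = 12)
  fit <- fit_cqtc(rows)
  l_hat <- dense_reml_loglik(fit$omega, fit$sigma2, rows,
                             fit$baseline_centre)
  expect_equal(l_hat, fit$logLik, tolerance = 1e-6)
  # 32 fixed perturbations of the variance parameters
  fac <- c(0.7, 0.9, 1.1, 1.4)
  grid <- expand.grid(f_int = fac, f_slope = fac, f_sig = c(0.9, 1.1))
  for (i in seq_len(nrow(grid))) {
    om <- fit$omega * tcrossprod(c(grid$f_int[i], grid$f_slope[i]))
    l_pert <- dense_reml_loglik(om, fit$sigma2 * grid$f_sig[i], rows,
                                fit$baseline_centre)
    expect_lte(l_pert, l_hat + 1e-8)
  }
})

test_that("fixed effects are invariant to the baseline centring constant", {
  rows <- simulated_rows(seed = 6)
  f1 <- fit_cqtc(rows)
  f2 <- fit_cqtc(rows, baseline_centre = f1$baseline_centre + 10)
  expect_equal(coef(f2)[["slope"]], coef(f1)[["slope"]], tolerance = 1e-6)
  expect_equal(coef(f2)[["baseline"]], coef(f1)[["baseline"]],
               tolerance = 1e-6)
  expect_equal(coef(f2)[["(Intercept)"]],
               coef(f1)[["(Intercept)"]] + 10 * coef(f1)[["baseline"]],
               tolerance = 1e-5)
})

test_that("degenerate designs raise estimation errors naming the deficiency", {
  rows <- exact_linear_rows()
  rows$conc <- 100
  expect_error(fit_cqtc(rows), "concentrations")
  one_subj <- exact_linear_rows(n_subj = 1)
  expect_error(fit_cqtc(one_subj), "2 subjects")
})

test_that("the fit is deterministic given the data", {
  rows <- simulated_rows(seed = 7)
  f1 <- fit_cqtc(rows)
  f2 <- fit_cqtc(rows)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$omega, f2$omega)
  expect_identical(f1$logLik, f2$logLik)
})

test_that("residuals, fitted values and BLUPs are consistent", {
  rows <- simulated_rows(seed = 8)
  fit <- fit_cqtc(rows)
  expect_equal(fitted(fit) + residuals(fit), rows$ddqtcf_ms,
               tolerance = 1e-10)
  # conditional residuals should be smaller in aggregate
  expect_lt(sum(residuals(fit, "conditional")^2),
            sum(residuals(fit)^2))
  expect_equal(nrow(fit$ranef), fit$n_subjects)
})
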