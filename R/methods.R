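## S3 methods for the fitted C-QTc model.

#' @export
print.cqt_fit <- function(x, digits = 4, ...) {
  cat("Linear mixed-effects C-QTcF model (REML)\n")
  if (!is.na(x$n_obs)) {
    cat(sprintf("  %d observations, %d subjects\n", x$n_obs, x$n_subjects))
  }
  cat("Fixed effects:\n")
  print(round(x$coefficients, digits))
  if (!is.null(x$omega)) {
    cat("Random-effect covariance (Omega):\n")
    print(signif(x$omega, digits))
    cat(sprintf("Residual SD: %.*f ms\n", digits, sqrt(x$sigma2)))
  }
  invisible(x)
}

#' @export
summary.cqt_fit <- function(object, level = object$level, ...) {
  se <- sqrt(diag(object$vcov))
  tval <- object$coefficients / ifelse(se > 0, se, NA)
  alpha <- 1 - level
  crit <- stats::qt(1 - alpha / 2, object$df)
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = se,
               Lower = object$coefficients - crit * se,
               Upper = object$coefficients + crit * se,
               `t value` = tval)
  structure(list(coefficients = tab, level = level, df = object$df,
                 omega = object$omega, sigma2 = object$sigma2,
                 logLik = object$logLik, n_obs = object$n_obs,
                 n_subjects = object$n_subjects,
                 baseline_centre = object$baseline_centre,
                 random = object$random),
            class = "summary.cqt_fit")
}

#' @export
print.summary.cqt_fit <- function(x, digits = 4, ...) {
  cat("Linear mixed-effects C-QTcF model (REML)\n")
  if (!is.na(x$n_obs)) {
    cat(sprintf("  %d observations, %d subjects; restricted logLik %.3f\n",
                x$n_obs, x$n_subjects, x$logLik))
  }
  cat(sprintf("Fixed effects (t intervals, df = %s, %.0f%% level):\n",
              format(x$df), 100 * x$level))
  print(round(x$coefficients, digits))
  if (!is.null(x$omega)) {
    cat("\nRandom-effect covariance (Omega):\n")
    print(signif(x$omega, digits))
    cat(sprintf("Residual variance sigma^2: %s ms^2\n",
                signif(x$sigma2, digits)))
  }
  if (is.finite(x$baseline_centre)) {
    cat(sprintf("Baseline QTcF centred at %.1f ms\n", x$baseline_centre))
  }
  invisible(x)
}

#' @export
coef.cqt_fit <- function(object, ...) object$coefficients

#' @export
vcov.cqt_fit <- function(object, ...) object$vcov

#' @export
logLik.cqt_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
confint.cqt_fit <- function(object, parm, level = object$level, ...) {
  se <- sqrt(diag(object$vcov))
  crit <- stats::qt(1 - (1 - level) / 2, object$df)
  ci <- cbind(object$coefficients - crit * se,
              object$coefficients + crit * se)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                         " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
fitted.cqt_fit <- function(object, ...) object$fitted

#' Residuals of a fitted C-QTc model
#'
#' @param object A `cqt_fit`.
#' @param type `"marginal"` (response minus the fixed-effect fit) or
#'   `"conditional"` (additionally subtracting the subject-level BLUP
#'   contribution).
#' @param ... Unused.
#' @return Numeric vector of residuals, ms.
#' @export
residuals.cqt_fit <- function(object, type = c("marginal", "conditional"),
                              ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "conditional" && !is.null(object$ranef)) {
    re <- object$ranef[as.character(object$data$subject_id), , drop = FALSE]
    contrib <- re[, 1]
    if (ncol(re) == 2L) contrib <- contrib + re[, 2] * object$data$conc
    r <- r - contrib
  }
  r
}

#' Predict mean ddQTcF with a two-sided confidence interval
#'
#' Evaluates \eqn{\theta_0 + \theta_1 C} at centred baseline 0 with
#' prediction variance \eqn{v_{00} + C^2 v_{11} + 2 C v_{01}} from the
#' fixed-effect covariance, and a two-sided t interval with the fit's
#' degrees of freedom (`n_subjects - p`).
#'
#' @param object A `cqt_fit`.
#' @param conc Concentration(s) of interest, ng/mL (>= 0).
#' @param level Two-sided confidence level (default: the fit's).
#' @param ... Unused.
#' @return A data.frame of class `cqt_prediction` with columns `conc`,
#'   `mean_ms`, `se_ms`, `ci_lower_ms`, `ci_upper_ms`, and attributes
#'   `level` and `df`.
#' @export
predict.cqt_fit <- function(object, conc, level = object$level, ...) {
  if (!is.numeric(conc) || any(!is.finite(conc)) || any(conc < 0)) {
    stop("`conc` must be non-negative and finite (ng/mL)", call. = FALSE)
  }
  b <- object$coefficients
  v <- object$vcov
  mean_ms <- b[[1]] + b[[2]] * conc
  var_ms <- v[1, 1] + conc^2 * v[2, 2] + 2 * conc * v[1, 2]
  se <- sqrt(pmax(var_ms, 0))
  crit <- stats::qt(1 - (1 - level) / 2, object$df)
  out <- data.frame(conc = conc, mean_ms = mean_ms, se_ms = se,
                    ci_lower_ms = mean_ms - crit * se,
                    ci_upper_ms = mean_ms + crit * se)
  structure(out, level = level, df = object$df,
            class = c("cqt_prediction", "data.frame"))
}

#' Construct a prediction row from published interval bounds
#'
#' Lets verdict functions be applied directly to a reported
#' "mean (lower, upper)" table cell.
#'
#' @param conc Concentration, ng/mL.
#' @param mean_ms,ci_lower_ms,ci_upper_ms Reported mean and two-sided
#'   bounds, ms.
#' @param level Confidence level of the reported interval.
#' @return A `cqt_prediction` data.frame.
#' @export
cqt_prediction <- function(conc, mean_ms, ci_lower_ms, ci_upper_ms,
                           level = 0.90) {
  stopifnot(all(ci_lower_ms <= mean_ms), all(mean_ms <= ci_upper_ms))
  structure(data.frame(conc = conc, mean_ms = mean_ms, se_ms = NA_real_,
                       ci_lower_ms = ci_lower_ms,
                       ci_upper_ms = ci_upper_ms),
            level = level, df = NA_real_,
            class = c("cqt_prediction", "data.frame"))
}

#' @export
print.cqt_prediction <- function(x, digits = 1, ...) {
  cat(sprintf("Mean ddQTcF (%.0f%% CI), ms:\n", 100 * attr(x, "level")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %8.1f ng/mL: %6.*f (%.*f, %.*f)\n", x$conc[i],
                digits, x$mean_ms[i], digits, x$ci_lower_ms[i],
                digits, x$ci_upper_ms[i]))
  }
  invisible(x)
}

#' Simulate responses from a fitted C-QTc model
#'
#' Parametric simulation at the design of the fitted data: new subject-
#' level random effects from the estimated Omega and residuals from the
#' estimated sigma^2 around the fixed-effect mean.
#'
#' @param object A `cqt_fit` fitted to data.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed (an integer), applied via [set.seed()].
#' @param ... Unused.
#' @return A data.frame with `nsim` columns of simulated `ddqtcf_ms`.
#' @export
simulate.cqt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$data)) {
    stop("simulate() requires a model fitted to data", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- object$data
  subj <- factor(rows$subject_id)
  m <- nlevels(subj)
  mu <- object$fitted
  out <- matrix(NA_real_, nrow(rows), nsim)
  for (k in seq_len(nsim)) {
    eta <- if (is.null(object$omega)) {
      matrix(0, m, 2)
    } else {
      rmvnorm_chol(m, pad_2x2(object$omega))
    }
    contrib <- eta[as.integer(subj), 1] +
      eta[as.integer(subj), 2] * rows$conc
    out[, k] <- mu + contrib +
      stats::rnorm(nrow(rows), 0, sqrt(object$sigma2))
  }
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted C-QTc model
#'
#' Scatter of observed ddQTcF against concentration with the fitted line,
#' its two-sided confidence band, and (optionally) concentration-decile
#' means with intervals, mirroring the standard exposure-response figure.
#'
#' @param x A `cqt_fit` fitted to data.
#' @param level Confidence level for the band.
#' @param deciles Overlay decile summaries (default `TRUE`).
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.cqt_fit <- function(x, level = x$level, deciles = TRUE, ...) {
  if (is.null(x$data)) stop("plot() requires a model fitted to data",
                            call. = FALSE)
  rows <- x$data
  grid <- seq(0, max(rows$conc), length.out = 100)
  pred <- predict(x, grid, level = level)
  graphics::plot(rows$conc, rows$ddqtcf_ms, col = "grey60", pch = 16,
                 cex = 0.6, xlab = "Concentration (ng/mL)",
                 ylab = expression(Delta * Delta * "QTcF (ms)"), ...)
  graphics::polygon(c(grid, rev(grid)),
                    c(pred$ci_lower_ms, rev(pred$ci_upper_ms)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(grid, pred$mean_ms, col = "steelblue4", lwd = 2)
  graphics::abline(h = c(0, 10), lty = c(3, 2))
  if (deciles && sum(rows$conc > 0) >= 10) {
    dec <- decile_summary(rows$conc, rows$ddqtcf_ms, level = level)
    graphics::points(dec$conc_mean, dec$ddqtcf_mean, pch = 19,
                     col = "purple")
    graphics::segments(dec$conc_mean, dec$ci_lower, dec$conc_mean,
                       dec$ci_upper, col = "purple")
  }
  invisible(x)
}

## internal: n draws from N(0, Sigma) via a PSD-safe square root
rmvnorm_chol <- function(n, sigma) {
  q <- nrow(sigma)
  if (all(sigma == 0)) return(matrix(0, n, q))
  L <- tryCatch(t(chol(sigma)), error = function(e) {
    ev <- eigen(sigma, symmetric = TRUE)
    ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), q)
  })
  matrix(stats::rnorm(n * q), n, q) %*% t(L)
}

pad_2x2 <- function(omega) {
  if (is.null(omega)) return(matrix(0, 2, 2))
  if (nrow(omega) == 2L) return(omega)
  out <- matrix(0, 2, 2)
  out[1, 1] <- omega[1, 1]
  out
}
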