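## Regulatory quantities: the concentration of interest, the 10-ms
## exclusion verdict, moxifloxacin assay sensitivity, and the paired-t
## exclusion power used for sample sizing.

#' Concentration of interest from a steady-state geometric mean Cmax
#'
#' The exposure at which the QTc effect must be bounded: the steady-state
#' geometric mean Cmax multiplied by a safety factor covering intrinsic and
#' extrinsic sources of exposure increase (drug-drug interactions, organ
#' impairment), conventionally 2. Reported to the nearest integer ng/mL;
#' the unrounded product is kept in the `"exact"` attribute.
#'
#' @param gmean_cmax_ss Steady-state geometric mean Cmax, ng/mL (> 0).
#' @param factor Multiplicative exposure margin (> 0), default 2.
#' @return The rounded concentration of interest, ng/mL.
#' @examples
#' concentration_of_interest(43.1)  # 86
#' @export
concentration_of_interest <- function(gmean_cmax_ss, factor = 2) {
  if (!is.numeric(gmean_cmax_ss) || any(gmean_cmax_ss <= 0) ||
      !is.numeric(factor) || any(factor <= 0)) {
    stop("`gmean_cmax_ss` and `factor` must be positive", call. = FALSE)
  }
  exact <- gmean_cmax_ss * factor
  structure(round(exact), exact = exact)
}

#' ICH E14-style exclusion of a QTc-prolonging effect
#'
#' A prolonging effect is excluded when the upper bound of the two-sided
#' confidence interval for mean ddQTcF at the concentration of interest is
#' strictly below the threshold (10 ms by convention).
#'
#' @param object A `cqt_fit` (with `conc` supplied) or a `cqt_prediction`.
#' @param conc Concentration of interest, ng/mL (ignored for a
#'   prediction input).
#' @param threshold_ms Exclusion threshold, ms (default 10).
#' @param level Two-sided confidence level (default 0.90).
#' @return A `cqt_verdict` list: `kind`, `conc`, `bound_ms` (the decisive
#'   interval bound), `threshold_ms`, `level`, `passed`.
#' @examples
#' p <- cqt_prediction(86, -2.3, -3.7, -0.9)
#' assess_no_prolongation(p)$passed
#' @export
assess_no_prolongation <- function(object, conc = NULL, threshold_ms = 10,
                                   level = 0.90) {
  pred <- verdict_prediction(object, conc, level)
  i <- which.max(pred$ci_upper_ms)
  new_verdict("no_prolongation", pred$conc[i], pred$ci_upper_ms[i],
              threshold_ms, attr(pred, "level"),
              passed = all(pred$ci_upper_ms < threshold_ms),
              direction = "<")
}

#' Assay sensitivity of the QT assay via the positive control
#'
#' The study can detect a small QTc effect when the lower bound of the
#' two-sided confidence interval for the positive control's ddQTcF at its
#' observed geometric mean Cmax is strictly above the threshold (5 ms by
#' convention).
#'
#' @param object A `cqt_fit` from positive-control (moxifloxacin) rows, or
#'   a `cqt_prediction`.
#' @param gmean_cmax Observed geometric mean Cmax of the positive control,
#'   ng/mL (ignored for a prediction input).
#' @param threshold_ms Sensitivity threshold, ms (default 5).
#' @param level Two-sided confidence level (default 0.90).
#' @return A `cqt_verdict` list; `passed` is `TRUE` when the lower bound
#'   exceeds `threshold_ms` strictly.
#' @examples
#' p <- cqt_prediction(2367.1, 13.0, 8.8, 17.2)
#' assess_assay_sensitivity(p)$passed
#' @export
assess_assay_sensitivity <- function(object, gmean_cmax = NULL,
                                     threshold_ms = 5, level = 0.90) {
  pred <- verdict_prediction(object, gmean_cmax, level)
  i <- which.min(pred$ci_lower_ms)
  new_verdict("assay_sensitivity", pred$conc[i], pred$ci_lower_ms[i],
              threshold_ms, attr(pred, "level"),
              passed = all(pred$ci_lower_ms > threshold_ms),
              direction = ">")
}

#' @export
print.cqt_verdict <- function(x, ...) {
  lab <- switch(x$kind,
                no_prolongation = "QTc effect exclusion",
                assay_sensitivity = "Assay sensitivity")
  cat(sprintf("%s at %.1f ng/mL: %s bound %.2f ms %s %.0f ms -> %s\n",
              lab, x$conc,
              if (x$direction == "<") "upper" else "lower",
              x$bound_ms, x$direction, x$threshold_ms,
              if (x$passed) "PASSED" else "NOT MET"))
  invisible(x)
}

#' Power of a paired-t exclusion of a QTc margin
#'
#' Probability that the one-sided upper `1 - alpha` confidence bound for
#' the mean paired ddQTcF excludes the margin, i.e.
#' \eqn{P(\bar x + t_{1-\alpha, n-1}\, s/\sqrt n < m)}, computed from the
#' noncentral t distribution with noncentrality
#' \eqn{(\mu - m) / (\sigma/\sqrt n)}.
#'
#' @param n Number of evaluable paired subjects (>= 2).
#' @param sd_ddqtcf Within-subject SD of ddQTcF, ms (> 0; the degenerate
#'   limit sd -> 0 returns 1 when the true effect is below the margin).
#' @param margin_ms Effect size to exclude, ms (default 10).
#' @param true_effect_ms True mean ddQTcF, ms (default 0).
#' @param alpha One-sided significance level (default 0.05, the one-sided
#'   complement of a two-sided 90% interval).
#' @return The exclusion power, a probability.
#' @examples
#' power_paired_exclusion(24, sd_ddqtcf = 8)
#' @export
power_paired_exclusion <- function(n, sd_ddqtcf, margin_ms = 10,
                                   true_effect_ms = 0, alpha = 0.05) {
  if (!is.numeric(n) || n < 2 || n != round(n)) {
    stop("`n` must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(sd_ddqtcf) || sd_ddqtcf < 0 || !is.finite(sd_ddqtcf)) {
    stop("`sd_ddqtcf` must be non-negative", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  if (sd_ddqtcf < 1e-12) return(as.numeric(true_effect_ms < margin_ms))
  df <- n - 1
  ncp <- (true_effect_ms - margin_ms) / (sd_ddqtcf / sqrt(n))
  stats::pt(-stats::qt(1 - alpha, df), df, ncp = ncp)
}

## ---- internal ---------------------------------------------------------

verdict_prediction <- function(object, conc, level) {
  if (inherits(object, "cqt_prediction")) return(object)
  if (inherits(object, "cqt_fit")) {
    if (is.null(conc)) {
      stop("a concentration must be supplied with a model fit",
           call. = FALSE)
    }
    return(predict(object, conc, level = level))
  }
  stop("`object` must be a cqt_fit or cqt_prediction", call. = FALSE)
}

new_verdict <- function(kind, conc, bound, threshold, level, passed,
                        direction) {
  structure(list(kind = kind, conc = conc, bound_ms = bound,
                 threshold_ms = threshold, level = level,
                 passed = passed, direction = direction),
            class = "cqt_verdict")
}
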