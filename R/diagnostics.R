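## Pre-modelling assumption checks. The underlying questions are graphical
## in routine practice; here each is made quantitative with a documented,
## configurable threshold so a pipeline can gate on it.

#' Heart-rate effect check
#'
#' QT correction by a fixed formula (Fridericia) presumes the drug does
#' not itself move heart rate materially. The check passes when the
#' absolute mean placebo-corrected, baseline-adjusted heart-rate change
#' (ddHR) is strictly below the threshold at every timepoint.
#'
#' @param data Data.frame with columns `time_h` and `ddhr_bpm`
#'   (subject-level rows; means are taken per timepoint).
#' @param threshold_bpm Threshold, beats/min (default 10).
#' @return A `cqt_check` list with the per-timepoint means, the maximum
#'   absolute mean, the offending timepoints, and `passed`.
#' @export
check_hr_effect <- function(data, threshold_bpm = 10) {
  stopifnot(is.data.frame(data),
            all(c("time_h", "ddhr_bpm") %in% names(data)))
  ok <- is.finite(data$ddhr_bpm)
  if (!any(ok)) stop("no ddHR values to check", call. = FALSE)
  means <- tapply(data$ddhr_bpm[ok], data$time_h[ok], mean)
  by_time <- data.frame(time_h = as.numeric(names(means)),
                        mean_ddhr_bpm = as.numeric(means))
  by_time <- by_time[order(by_time$time_h), ]
  failed <- by_time$time_h[abs(by_time$mean_ddhr_bpm) >= threshold_bpm]
  structure(list(type = "hr_effect", by_time = by_time,
                 max_abs_bpm = max(abs(by_time$mean_ddhr_bpm)),
                 threshold_bpm = threshold_bpm, failed_times = failed,
                 passed = length(failed) == 0),
            class = "cqt_check")
}

#' Hysteresis check: concordance of concentration and effect time courses
#'
#' A direct-effect model presumes no material lag between the
#' concentration peak and the ddQTcF peak. Peak times are taken as the
#' earliest maximum on the shared nominal grid (a deterministic tie rule
#' on coarse grids); the check flags when the effect peak trails the
#' concentration peak by more than the tolerance.
#'
#' @param time_h Shared nominal time grid (>= 4 points).
#' @param mean_conc Mean concentration time course.
#' @param mean_ddqtcf Mean ddQTcF time course.
#' @param lag_tolerance_h Maximum unflagged lag, hours (default 1).
#' @return A `cqt_check` list with both peak times, `lag_h` and `flagged`.
#' @export
check_hysteresis <- function(time_h, mean_conc, mean_ddqtcf,
                             lag_tolerance_h = 1) {
  if (length(time_h) < 4 || length(mean_conc) != length(time_h) ||
      length(mean_ddqtcf) != length(time_h)) {
    stop("time courses must share a nominal grid of >= 4 points",
         call. = FALSE)
  }
  o <- order(time_h)
  time_h <- time_h[o]
  t_peak_conc <- time_h[which.max(mean_conc[o])]
  t_peak_ddqtcf <- time_h[which.max(mean_ddqtcf[o])]
  lag <- t_peak_ddqtcf - t_peak_conc
  structure(list(type = "hysteresis", t_peak_conc_h = t_peak_conc,
                 t_peak_ddqtcf_h = t_peak_ddqtcf, lag_h = lag,
                 lag_tolerance_h = lag_tolerance_h,
                 flagged = lag > lag_tolerance_h),
            class = "cqt_check")
}

#' Linearity check: LOESS against the straight line
#'
#' Fits a local-linear LOESS (tri-cube weights) and a simple linear
#' regression of ddQTcF on concentration, and reports the maximum absolute
#' discrepancy between the two over an evenly spaced grid within the
#' observed concentration range. Flagged when the discrepancy exceeds
#' `sd_fraction` of the linear fit's residual standard deviation (plus a
#' small numerical floor, so exactly linear data are never flagged). The
#' decision is invariant to affine rescaling of the concentration axis.
#'
#' @param conc,ddqtcf Observation vectors (>= 20 rows spanning >= 5
#'   distinct concentrations).
#' @param span LOESS span (default 0.75).
#' @param grid_n Number of grid points (default 50).
#' @param sd_fraction Flagging fraction of the residual SD (default 0.5).
#' @return A `cqt_check` list with `max_discrepancy_ms`,
#'   `residual_sd_ms`, the grid curves and `flagged`.
#' @export
check_linearity <- function(conc, ddqtcf, span = 0.75, grid_n = 50,
                            sd_fraction = 0.5) {
  ok <- is.finite(conc) & is.finite(ddqtcf)
  conc <- conc[ok]
  ddqtcf <- ddqtcf[ok]
  if (length(conc) < 20 || length(unique(conc)) < 5) {
    stop("linearity check needs >= 20 rows over >= 5 distinct ",
         "concentrations", call. = FALSE)
  }
  lin <- stats::lm(ddqtcf ~ conc)
  lo <- stats::loess(ddqtcf ~ conc, span = span, degree = 1,
                     family = "gaussian",
                     control = stats::loess.control(surface = "direct"))
  grid <- seq(min(conc), max(conc), length.out = grid_n)
  f_lin <- stats::predict(lin, data.frame(conc = grid))
  f_lo <- stats::predict(lo, data.frame(conc = grid))
  disc <- max(abs(f_lo - f_lin))
  sd_ref <- stats::sigma(lin)
  floor_tol <- 1e-8 * max(1, diff(range(ddqtcf)))
  structure(list(type = "linearity", max_discrepancy_ms = disc,
                 residual_sd_ms = sd_ref, sd_fraction = sd_fraction,
                 span = span,
                 grid = data.frame(conc = grid, linear = f_lin,
                                   loess = f_lo),
                 flagged = disc > sd_fraction * sd_ref + floor_tol),
            class = "cqt_check")
}

#' Covariate impact check on the dQTcF time course
#'
#' Compares group-mean dQTcF time courses (e.g. with/without an ACTH
#' challenge, or by diet) and reports the maximum absolute between-group
#' difference at any shared timepoint, flagged against the same
#' residual-SD fraction rule as the linearity check. No model covariate is
#' added; the check documents whether one would have been needed.
#'
#' @param data Data.frame with `time_h`, `dqtcf_ms` and a grouping column.
#' @param group Name of the grouping column.
#' @param sd_fraction Flagging fraction of the pooled residual SD about
#'   group-by-time means (default 0.5).
#' @return A `cqt_check` list with the group-mean courses,
#'   `max_group_difference_ms` and `flagged`.
#' @export
check_covariate_impact <- function(data, group, sd_fraction = 0.5) {
  stopifnot(is.data.frame(data),
            all(c("time_h", "dqtcf_ms", group) %in% names(data)))
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  cell <- interaction(g, data$time_h, drop = TRUE)
  cell_mean <- tapply(data$dqtcf_ms, cell, mean)
  resid <- data$dqtcf_ms - as.numeric(cell_mean[as.character(cell)])
  sd_ref <- stats::sd(resid)
  means <- tapply(data$dqtcf_ms, list(g, data$time_h), mean)
  diffs <- apply(means, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) < 2) return(NA_real_)
    diff(range(col))
  })
  max_diff <- max(diffs, na.rm = TRUE)
  floor_tol <- 1e-8 * max(1, diff(range(data$dqtcf_ms)))
  structure(list(type = "covariate_impact", group = group,
                 group_means = means, max_group_difference_ms = max_diff,
                 residual_sd_ms = sd_ref, sd_fraction = sd_fraction,
                 flagged = max_diff > sd_fraction * sd_ref + floor_tol),
            class = "cqt_check")
}

#' Concentration-decile summary of the exposure-response data
#'
#' Rows with positive concentration are ranked by concentration and split
#' into 10 near-equal groups (sizes differ by at most one; the remainder
#' is spread over the lowest groups). Per group: mean concentration, mean
#' ddQTcF and a two-sided t interval. The decile means overlaid on the
#' model line are the standard goodness-of-fit display.
#'
#' @param conc,ddqtcf Observation vectors (>= 10 positive-concentration
#'   rows).
#' @param level Confidence level (default 0.90).
#' @return A data.frame with one row per decile: `decile`, `n`,
#'   `conc_mean`, `ddqtcf_mean`, `ci_lower`, `ci_upper`. Groups of size 1
#'   carry `NA` bounds.
#' @export
decile_summary <- function(conc, ddqtcf, level = 0.90) {
  ok <- is.finite(conc) & is.finite(ddqtcf) & conc > 0
  conc <- conc[ok]
  ddqtcf <- ddqtcf[ok]
  n <- length(conc)
  if (n < 10) stop("decile summary needs >= 10 positive-concentration ",
                   "rows", call. = FALSE)
  o <- order(conc)
  sizes <- rep(n %/% 10, 10)
  r <- n %% 10
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1
  gid <- rep(seq_len(10), sizes)
  alpha <- 1 - level
  out <- do.call(rbind, lapply(seq_len(10), function(g) {
    ii <- o[gid == g]
    m <- mean(ddqtcf[ii])
    k <- length(ii)
    if (k >= 2) {
      hw <- stats::qt(1 - alpha / 2, k - 1) * stats::sd(ddqtcf[ii]) /
        sqrt(k)
    } else {
      hw <- NA_real_
    }
    data.frame(decile = g, n = k, conc_mean = mean(conc[ii]),
               ddqtcf_mean = m, ci_lower = m - hw, ci_upper = m + hw)
  }))
  reset_rows(out)
}

#' Consolidated pre-modelling diagnostic report
#'
#' Runs the heart-rate, hysteresis, linearity and decile checks on
#' model-ready rows (the output of [derive_cqt_rows()], which carries
#' `ddhr_bpm` alongside `ddqtcf_ms`).
#'
#' @param rows Model-ready rows.
#' @param hr_threshold_bpm,lag_tolerance_h,span,sd_fraction,level
#'   Thresholds passed to the individual checks.
#' @return A `cqt_diagnostics` list with elements `hr`, `hysteresis`,
#'   `linearity`, `deciles`.
#' @export
cqt_diagnostics <- function(rows, hr_threshold_bpm = 10,
                            lag_tolerance_h = 1, span = 0.75,
                            sd_fraction = 0.5, level = 0.90) {
  stopifnot(is.data.frame(rows))
  hr <- if ("ddhr_bpm" %in% names(rows)) {
    check_hr_effect(rows, hr_threshold_bpm)
  }
  post <- rows[rows$time_h > 0, , drop = FALSE]
  conc_course <- tapply(post$conc, post$time_h, mean)
  qtc_course <- tapply(post$ddqtcf_ms, post$time_h, mean)
  hysteresis <- check_hysteresis(as.numeric(names(conc_course)),
                                 as.numeric(conc_course),
                                 as.numeric(qtc_course),
                                 lag_tolerance_h)
  linearity <- check_linearity(rows$conc, rows$ddqtcf_ms, span = span,
                               sd_fraction = sd_fraction)
  deciles <- decile_summary(rows$conc, rows$ddqtcf_ms, level = level)
  structure(list(hr = hr, hysteresis = hysteresis, linearity = linearity,
                 deciles = deciles),
            class = "cqt_diagnostics")
}

#' @export
print.cqt_check <- function(x, ...) {
  msg <- switch(x$type,
    hr_effect = sprintf(
      "HR effect: max |mean ddHR| %.2f bpm (threshold %g) -> %s",
      x$max_abs_bpm, x$threshold_bpm,
      if (x$passed) "passed" else "FAILED"),
    hysteresis = sprintf(
      "Hysteresis: conc peak %g h, ddQTcF peak %g h, lag %g h -> %s",
      x$t_peak_conc_h, x$t_peak_ddqtcf_h, x$lag_h,
      if (x$flagged) "FLAGGED" else "not flagged"),
    linearity = sprintf(
      "Linearity: max |LOESS - linear| %.3f ms vs %.3f ms (%.2g x resid SD) -> %s",
      x$max_discrepancy_ms, x$sd_fraction * x$residual_sd_ms,
      x$sd_fraction, if (x$flagged) "FLAGGED" else "not flagged"),
    covariate_impact = sprintf(
      "Covariate impact (%s): max group difference %.3f ms -> %s",
      x$group, x$max_group_difference_ms,
      if (x$flagged) "FLAGGED" else "not flagged"))
  cat(msg, "\n")
  invisible(x)
}

#' @export
print.cqt_diagnostics <- function(x, ...) {
  cat("Pre-modelling diagnostics\n")
  if (!is.null(x$hr)) print(x$hr)
  print(x$hysteresis)
  print(x$linearity)
  cat(sprintf("Deciles: %d groups, %d rows\n", nrow(x$deciles),
              sum(x$deciles$n)))
  invisible(x)
}

#' Plot the diagnostic report
#'
#' Two-panel base-graphics display: LOESS versus linear fit, and the
#' concentration/ddQTcF mean time courses used by the hysteresis check.
#'
#' @param x A `cqt_diagnostics`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.cqt_diagnostics <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  g <- x$linearity$grid
  graphics::plot(g$conc, g$linear, type = "l", lwd = 2,
                 xlab = "Concentration (ng/mL)",
                 ylab = expression(Delta * Delta * "QTcF (ms)"),
                 main = "Linearity")
  graphics::lines(g$conc, g$loess, col = "red", lty = 2, lwd = 2)
  graphics::legend("topleft", c("linear", "LOESS"), lty = c(1, 2),
                   col = c("black", "red"), bty = "n")
  graphics::points(x$deciles$conc_mean, x$deciles$ddqtcf_mean,
                   pch = 19, col = "purple")
  h <- x$hysteresis
  graphics::plot(NA, xlim = range(0, h$t_peak_conc_h, h$t_peak_ddqtcf_h),
                 ylim = c(0, 1), xlab = "Time (h)", ylab = "",
                 yaxt = "n", main = "Peak concordance")
  graphics::abline(v = h$t_peak_conc_h, col = "steelblue", lwd = 2)
  graphics::abline(v = h$t_peak_ddqtcf_h, col = "purple", lwd = 2,
                   lty = 2)
  graphics::legend("topright", c("conc peak", "ddQTcF peak"),
                   col = c("steelblue", "purple"), lty = c(1, 2),
                   bty = "n")
  invisible(x)
}
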