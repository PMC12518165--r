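## Non-compartmental pharmacokinetic analysis of a single concentration-
## time profile, plus geometric summary statistics and a dose-
## proportionality screen.

#' Non-compartmental analysis of one concentration-time profile
#'
#' Computes the standard single-dose NCA parameters:
#' \itemize{
#'   \item `cmax` / `tmax_h`: observed maximum (earliest time on ties);
#'   \item `auc_last`: linear-up/log-down trapezoid to the last positive
#'     concentration (logarithmic interpolation on declining segments
#'     between positive values, linear otherwise);
#'   \item `lambda_z`: terminal log-linear slope over the candidate window
#'     with the best adjusted R-squared among contiguous terminal windows
#'     of >= 3 positive-concentration points after (excluding) tmax, ties
#'     to the longer window. When fewer than 3 such points exist, the
#'     terminal window from tmax onward (>= 2 points) is used as a
#'     documented fallback;
#'   \item `auc_inf = auc_last + C_last / lambda_z`, `t_half = ln 2 /
#'     lambda_z`, and the extrapolated AUC fraction.
#' }
#' A non-positive terminal slope (e.g. a flat profile) leaves `auc_inf`
#' and `t_half_h` undefined (`NA`) with the reason recorded.
#'
#' @param times_h Strictly increasing sampling times, hours (>= 3 points).
#' @param concs Concentrations, ng/mL (>= 0; at least one positive).
#' @return An object of class `nca_result`: a list with `cmax`, `tmax_h`,
#'   `auc_last`, `auc_inf`, `lambda_z`, `t_half_h`, `n_lambda_points`,
#'   `extrapolated_fraction`, `lambda_reason`.
#' @examples
#' r <- nca_profile(c(0, 1, 2), c(0, 10, 5))
#' r$auc_last  # 5 + 5/log(2)
#' r$t_half_h  # 1
#' @export
nca_profile <- function(times_h, concs) {
  if (length(times_h) != length(concs) || length(times_h) < 3) {
    stop("need >= 3 matched time/concentration points", call. = FALSE)
  }
  if (any(diff(times_h) <= 0)) {
    stop("`times_h` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(concs)) || any(concs < 0)) {
    stop("`concs` must be finite and non-negative", call. = FALSE)
  }
  if (all(concs == 0)) {
    stop("no positive concentrations in the profile", call. = FALSE)
  }

  imax <- which.max(concs)            # earliest maximum on ties
  cmax <- concs[imax]
  tmax <- times_h[imax]
  ilast <- max(which(concs > 0))

  auc_last <- 0
  for (i in seq_len(ilast - 1)) {
    c1 <- concs[i]
    c2 <- concs[i + 1]
    dt <- times_h[i + 1] - times_h[i]
    auc_last <- auc_last +
      if (c2 < c1 && c2 > 0 && c1 > 0) {
        dt * (c1 - c2) / log(c1 / c2)  # log-down
      } else {
        dt * (c1 + c2) / 2             # linear up / zero boundary
      }
  }

  lam <- terminal_slope(times_h, concs, imax, ilast)
  if (is.na(lam$lambda_z)) {
    auc_inf <- NA_real_
    t_half <- NA_real_
    extrap <- NA_real_
  } else {
    auc_inf <- auc_last + concs[ilast] / lam$lambda_z
    t_half <- log(2) / lam$lambda_z
    extrap <- (auc_inf - auc_last) / auc_inf
  }
  structure(list(cmax = cmax, tmax_h = tmax, auc_last = auc_last,
                 auc_inf = auc_inf, lambda_z = lam$lambda_z,
                 t_half_h = t_half, n_lambda_points = lam$n_points,
                 extrapolated_fraction = extrap,
                 lambda_reason = lam$reason),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("NCA: Cmax %.4g at %.3g h; AUClast %.5g h*ng/mL\n",
              x$cmax, x$tmax_h, x$auc_last))
  if (is.na(x$lambda_z)) {
    cat("  terminal phase unfit:", x$lambda_reason, "\n")
  } else {
    cat(sprintf(
      "  lambda_z %.5g /h (%d pts), t1/2 %.4g h, AUCinf %.5g (%.1f%% extrap)\n",
      x$lambda_z, x$n_lambda_points, x$t_half_h, x$auc_inf,
      100 * x$extrapolated_fraction))
  }
  invisible(x)
}

#' Per-subject NCA over a long-format PK dataset
#'
#' @param conc PK records data.frame (see [read_conc_csv()]).
#' @param analyte Analyte to analyse (default `"drug"`).
#' @return A data.frame with one row per subject x treatment (x sampling
#'   day, for a multiple-dose dataset carrying a `day` column) and the
#'   [nca_profile()] parameters as columns.
#' @export
nca_by_subject <- function(conc, analyte = "drug") {
  stopifnot(is.data.frame(conc))
  pk <- conc[conc$analyte == analyte & conc$time_h >= 0, , drop = FALSE]
  if (nrow(pk) == 0) stop("no PK records for analyte '", analyte, "'",
                          call. = FALSE)
  if (is.null(pk$day)) pk$day <- 1
  keys <- unique(pk[c("subject_id", "treatment", "day")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- pk[pk$subject_id == keys$subject_id[i] &
                pk$treatment == keys$treatment[i] &
                pk$day == keys$day[i], , drop = FALSE]
    sub <- sub[order(sub$time_h), ]
    r <- nca_profile(sub$time_h, sub$conc)
    data.frame(subject_id = keys$subject_id[i],
               treatment = keys$treatment[i], day = keys$day[i],
               cmax = r$cmax, tmax_h = r$tmax_h, auc_last = r$auc_last,
               auc_inf = r$auc_inf, lambda_z = r$lambda_z,
               t_half_h = r$t_half_h,
               extrapolated_fraction = r$extrapolated_fraction)
  }))
  reset_rows(out)
}

#' Geometric mean and geometric coefficient of variation
#'
#' `gmean = exp(mean(log v))`;
#' `gcv_percent = 100 * sqrt(exp(s^2) - 1)` with `s` the (n-1) sample SD
#' of `log v` — the conventional presentation of log-normally distributed
#' PK parameters.
#'
#' @param values Positive values, `n >= 2`.
#' @return A list with `gmean`, `gcv_percent` and `n`.
#' @examples
#' geometric_summary(c(100, 400))  # gmean 200, gCV% about 127
#' @export
geometric_summary <- function(values) {
  if (length(values) < 2 || any(!is.finite(values)) || any(values <= 0)) {
    stop("`values` must be >= 2 positive finite numbers", call. = FALSE)
  }
  lv <- log(values)
  s2 <- stats::var(lv)
  list(gmean = exp(mean(lv)),
       gcv_percent = 100 * sqrt(exp(s2) - 1),
       n = length(values))
}

#' Dose-proportionality screen on geometric mean exposure
#'
#' Dose-normalised geometric mean ratios relative to the lowest dose, for
#' Cmax and (optionally) AUCinf, flagged when outside the acceptance band.
#'
#' @param dose_mg Dose levels (>= 2).
#' @param cmax_gmean Geometric mean Cmax per dose.
#' @param aucinf_gmean Optional geometric mean AUCinf per dose.
#' @param band Acceptance band for the normalised ratio
#'   (default `c(0.8, 1.25)`).
#' @return A data.frame with one row per dose: the normalised ratios and
#'   per-parameter flags.
#' @examples
#' dose_proportionality(c(16, 32), c(180.7, 412.1))
#' @export
dose_proportionality <- function(dose_mg, cmax_gmean, aucinf_gmean = NULL,
                                 band = c(0.8, 1.25)) {
  if (length(dose_mg) < 2 || length(cmax_gmean) != length(dose_mg)) {
    stop("need >= 2 dose levels with matching geometric means",
         call. = FALSE)
  }
  if (any(!is.finite(dose_mg)) || any(dose_mg <= 0) ||
      any(!is.finite(cmax_gmean)) || any(cmax_gmean <= 0)) {
    stop("doses and geometric means must be positive", call. = FALSE)
  }
  o <- order(dose_mg)
  ref <- o[1]
  norm_ratio <- function(g) (g / dose_mg) / (g[ref] / dose_mg[ref])
  out <- data.frame(dose_mg = dose_mg,
                    cmax_ratio = norm_ratio(cmax_gmean))
  out$cmax_flagged <- out$cmax_ratio < band[1] | out$cmax_ratio > band[2]
  if (!is.null(aucinf_gmean)) {
    out$aucinf_ratio <- norm_ratio(aucinf_gmean)
    out$aucinf_flagged <- out$aucinf_ratio < band[1] |
      out$aucinf_ratio > band[2]
  }
  out[o, , drop = FALSE]
}

#' Predicted steady-state accumulation ratio for once-daily dosing
#'
#' `1 / (1 - 2^(-tau / t_half))`: the factor by which trough/average
#' exposure accumulates at steady state for a drug with terminal
#' half-life `t_half` dosed every `tau` hours.
#'
#' @param t_half_h Terminal half-life, hours (> 0).
#' @param tau_h Dosing interval, hours (default 24).
#' @return The accumulation ratio.
#' @examples
#' accumulation_ratio(29)  # about 2.3
#' @export
accumulation_ratio <- function(t_half_h, tau_h = 24) {
  if (any(t_half_h <= 0) || any(tau_h <= 0)) {
    stop("half-life and dosing interval must be positive", call. = FALSE)
  }
  1 / (1 - 2^(-tau_h / t_half_h))
}

## ---- internal ---------------------------------------------------------

## All suffix windows are scored at once via reverse cumulative sums, so
## the candidate search stays O(n) even on densely sampled profiles.
terminal_slope <- function(times_h, concs, imax, ilast) {
  pos_after <- which(concs > 0 & seq_along(concs) > imax &
                       seq_along(concs) <= ilast)
  suffix_fits <- function(ii) {
    t <- times_h[ii]
    lc <- log(concs[ii])
    rsum <- function(x) rev(cumsum(rev(x)))
    n <- rev(seq_along(ii))
    st <- rsum(t); st2 <- rsum(t^2)
    sy <- rsum(lc); sy2 <- rsum(lc^2)
    sty <- rsum(t * lc)
    sxx <- st2 - st^2 / n
    syy <- sy2 - sy^2 / n
    sxy <- sty - st * sy / n
    slope <- sxy / sxx
    r2 <- sxy^2 / (sxx * syy)
    r2adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
    data.frame(n = n, slope = slope, r2adj = r2adj)
  }
  if (length(pos_after) >= 3) {
    w <- suffix_fits(pos_after)
    w <- w[w$n >= 3 & is.finite(w$r2adj) & w$slope < 0, , drop = FALSE]
    if (nrow(w) > 0) {
      best <- w[w$r2adj > max(w$r2adj) - 1e-9, , drop = FALSE]
      best <- best[which.max(best$n), ]     # ties -> longer window
      return(list(lambda_z = -best$slope, n_points = best$n,
                  reason = NA_character_))
    }
  }
  ## fallback: terminal window from tmax onward (>= 2 points)
  ii <- which(concs > 0 & seq_along(concs) >= imax &
                seq_along(concs) <= ilast)
  if (length(ii) >= 2) {
    ft <- stats::lm(log(concs[ii]) ~ times_h[ii])
    slope <- stats::coef(ft)[[2]]
    if (is.finite(slope) && slope < 0) {
      return(list(lambda_z = -slope, n_points = length(ii),
                  reason = NA_character_))
    }
  }
  list(lambda_z = NA_real_, n_points = 0L,
       reason = "terminal log-linear slope non-negative or window unfit")
}
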