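## ECG interval derivation: HR, QTcF, baseline adjustment and placebo
## correction, producing model-ready concentration/ddQTcF observations.

#' Heart rate from the RR interval
#'
#' `HR = 60 / RR` with RR in seconds, i.e. `60 / (rr_ms / 1000)` beats/min.
#'
#' @param rr_ms RR interval(s), ms (> 0).
#' @return Heart rate, beats per minute.
#' @examples
#' heart_rate(c(1000, 800, 500))  # 60, 75, 120 bpm
#' @export
heart_rate <- function(rr_ms) {
  if (!is.numeric(rr_ms) || any(!is.finite(rr_ms)) || any(rr_ms <= 0)) {
    stop("`rr_ms` must be positive and finite", call. = FALSE)
  }
  60 / (rr_ms / 1000)
}

#' Fridericia heart-rate correction of the QT interval
#'
#' `QTcF = QT / (RR / 1000)^(1/3)` with both intervals in ms. At
#' RR = 1000 ms (60 bpm) the correction is the identity.
#'
#' @param qt_ms QT interval(s), ms (> 0).
#' @param rr_ms RR interval(s), ms (> 0).
#' @return QTcF, ms.
#' @examples
#' fridericia(400, 1000)  # 400
#' fridericia(350, 729)   # 350 / 0.9
#' @export
fridericia <- function(qt_ms, rr_ms) {
  if (!is.numeric(qt_ms) || any(!is.finite(qt_ms)) || any(qt_ms <= 0)) {
    stop("`qt_ms` must be positive and finite", call. = FALSE)
  }
  if (!is.numeric(rr_ms) || any(!is.finite(rr_ms)) || any(rr_ms <= 0)) {
    stop("`rr_ms` must be positive and finite", call. = FALSE)
  }
  qt_ms / (rr_ms / 1000)^(1 / 3)
}

#' Derive HR and QTcF for every ECG record
#'
#' @param ecg ECG records data.frame (see [read_ecg_csv()]).
#' @return The same data.frame with `hr_bpm` and `qtcf_ms` columns added.
#' @export
derive_qtcf <- function(ecg) {
  stopifnot(is.data.frame(ecg))
  need <- setdiff(ECG_COLUMNS, names(ecg))
  if (length(need)) {
    stop("ECG data lacks column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ecg$hr_bpm <- heart_rate(ecg$rr_ms)
  ecg$qtcf_ms <- fridericia(ecg$qt_ms, ecg$rr_ms)
  ecg
}

#' Baseline-adjust derived ECG records
#'
#' The baseline for each subject x treatment x period is the arithmetic
#' mean of the pre-dose (`time_h <= 0`) QTcF replicates; `dqtcf_ms` is the
#' record's QTcF minus that baseline. The identical adjustment is applied
#' to heart rate (`dhr_bpm`). Subject x periods with no pre-dose record are
#' excluded with a warning.
#'
#' @param decg Output of [derive_qtcf()].
#' @param baseline_rule `"day1"` (default): all days of a period share the
#'   Day-1 pre-dose baseline, the convention for a multiple-dose study
#'   analysed against the pre-treatment state. `"daily"`: each day uses its
#'   own pre-dose records.
#' @return `decg` with `baseline_qtcf_ms`, `dqtcf_ms`, `baseline_hr_bpm`
#'   and `dhr_bpm` added; excluded rows are reported via the
#'   `"n_excluded"` attribute.
#' @export
baseline_adjust <- function(decg, baseline_rule = c("day1", "daily")) {
  baseline_rule <- match.arg(baseline_rule)
  stopifnot(is.data.frame(decg), all(c("qtcf_ms", "hr_bpm") %in% names(decg)))
  grp_cols <- c("subject_id", "treatment", "period")
  if (baseline_rule == "daily") grp_cols <- c(grp_cols, "day")
  grp <- interaction(decg[grp_cols], drop = TRUE, lex.order = TRUE)

  pre <- decg$time_h <= 0
  if (baseline_rule == "day1") pre <- pre & decg$day == 1
  base_qtcf <- tapply(decg$qtcf_ms[pre], grp[pre], mean)
  base_hr   <- tapply(decg$hr_bpm[pre], grp[pre], mean)

  decg$baseline_qtcf_ms <- as.numeric(base_qtcf[as.character(grp)])
  decg$baseline_hr_bpm  <- as.numeric(base_hr[as.character(grp)])
  missing_base <- is.na(decg$baseline_qtcf_ms)
  if (any(missing_base)) {
    dropped <- unique(as.character(grp)[missing_base])
    warning(length(dropped), " subject x period group(s) excluded: ",
            "no pre-dose baseline record", call. = FALSE)
  }
  decg$dqtcf_ms <- decg$qtcf_ms - decg$baseline_qtcf_ms
  decg$dhr_bpm  <- decg$hr_bpm - decg$baseline_hr_bpm
  out <- decg[!missing_base, , drop = FALSE]
  attr(out, "n_excluded") <- sum(missing_base)
  reset_rows(out)
}

#' Placebo-correct a crossover study (time-matched within subject)
#'
#' For each subject, active treatment and nominal time, the placebo-
#' corrected effect is
#' `ddqtcf = dqtcf(active) - dqtcf(placebo at the same nominal time)`,
#' using the subject's own placebo period. Because the match is
#' time-matched within subject, diurnal QTc variation common to both
#' periods cancels. Matching is exact on (`day`, `time_h`); active rows
#' without a placebo match are dropped and counted. The same correction is
#' applied to heart rate (`ddhr_bpm`).
#'
#' @param adj Output of [baseline_adjust()].
#' @param placebo Treatment label of the placebo arm.
#' @return A data.frame of model-ready rows (`subject_id`, `treatment`,
#'   `period`, `day`, `time_h`, `baseline_qtcf_ms`, `dqtcf_ms`,
#'   `ddqtcf_ms`, `ddhr_bpm`) with a `"dropped"` attribute counting
#'   unmatched active rows. Only active-arm rows are returned.
#' @export
placebo_correct_crossover <- function(adj, placebo = "placebo") {
  stopifnot(is.data.frame(adj), "dqtcf_ms" %in% names(adj))
  plc <- adj[adj$treatment == placebo, , drop = FALSE]
  act <- adj[adj$treatment != placebo, , drop = FALSE]
  if (nrow(plc) == 0) {
    stop("crossover placebo correction requires a '", placebo, "' arm",
         call. = FALSE)
  }
  no_placebo <- setdiff(unique(act$subject_id), unique(plc$subject_id))
  if (length(no_placebo) > 0) {
    warning("subject(s) without a placebo period dropped: ",
            paste(no_placebo, collapse = ", "), call. = FALSE)
  }
  key_plc <- paste(plc$subject_id, plc$day, plc$time_h, sep = "\r")
  key_act <- paste(act$subject_id, act$day, act$time_h, sep = "\r")
  idx <- match(key_act, key_plc)
  matched <- !is.na(idx)
  out <- act[matched, c("subject_id", "treatment", "period", "day",
                        "time_h", "baseline_qtcf_ms", "dqtcf_ms"),
             drop = FALSE]
  out$ddqtcf_ms <- act$dqtcf_ms[matched] - plc$dqtcf_ms[idx[matched]]
  out$ddhr_bpm  <- act$dhr_bpm[matched] - plc$dhr_bpm[idx[matched]]
  out$placebo_baseline_qtcf_ms <- plc$baseline_qtcf_ms[idx[matched]]
  attr(out, "dropped") <- sum(!matched)
  reset_rows(out)
}

#' Placebo-correct a parallel-group study (pooled placebo arm)
#'
#' For an active-arm record, `ddqtcf = dqtcf - mean(dqtcf)` over all
#' pooled placebo subjects at the same `day` and nominal `time_h`. Active
#' rows with no placebo record at the matched time are dropped and counted.
#'
#' @param adj Output of [baseline_adjust()].
#' @param placebo Treatment label of the placebo arm.
#' @param by_cohort If `TRUE` and `adj` carries a `cohort` column, placebo
#'   means are computed within cohort instead of pooled across cohorts.
#' @return As [placebo_correct_crossover()].
#' @export
placebo_correct_parallel <- function(adj, placebo = "placebo",
                                     by_cohort = FALSE) {
  stopifnot(is.data.frame(adj), "dqtcf_ms" %in% names(adj))
  plc <- adj[adj$treatment == placebo, , drop = FALSE]
  act <- adj[adj$treatment != placebo, , drop = FALSE]
  if (nrow(plc) == 0) {
    stop("parallel-design placebo correction requires a non-empty '",
         placebo, "' arm", call. = FALSE)
  }
  cohort_key <- function(df) {
    if (by_cohort) {
      if (is.null(df$cohort)) {
        stop("`by_cohort = TRUE` requires a `cohort` column", call. = FALSE)
      }
      df$cohort
    } else {
      ""
    }
  }
  key_plc <- paste(cohort_key(plc), plc$day, plc$time_h, sep = "\r")
  key_act <- paste(cohort_key(act), act$day, act$time_h, sep = "\r")
  mean_plc_qtcf <- tapply(plc$dqtcf_ms, key_plc, mean)
  mean_plc_hr   <- tapply(plc$dhr_bpm, key_plc, mean)
  m_qtcf <- as.numeric(mean_plc_qtcf[key_act])
  m_hr   <- as.numeric(mean_plc_hr[key_act])
  matched <- !is.na(m_qtcf)
  keep_cols <- c("subject_id", "treatment", "period", "day", "time_h",
                 "baseline_qtcf_ms", "dqtcf_ms")
  if (by_cohort) keep_cols <- c(keep_cols, "cohort")
  out <- act[matched, keep_cols, drop = FALSE]
  out$ddqtcf_ms <- act$dqtcf_ms[matched] - m_qtcf[matched]
  out$ddhr_bpm  <- act$dhr_bpm[matched] - m_hr[matched]
  if (any(!matched)) {
    warning(sum(!matched),
            " active row(s) without a time-matched placebo mean dropped",
            call. = FALSE)
  }
  attr(out, "dropped") <- sum(!matched)
  reset_rows(out)
}

#' Attach time-matched drug concentrations to placebo-corrected rows
#'
#' Each ddQTcF row gains the same-subject, same-treatment, same-day,
#' same-nominal-time concentration of `analyte`. Pre-dose rows
#' (`time_h <= 0`) carry concentration 0 by definition of a single-dose
#' period; post-dose rows without a matching PK sample are dropped and
#' counted.
#'
#' @param rows Output of a placebo-correction function.
#' @param conc PK records data.frame (see [read_conc_csv()]).
#' @param analyte Analyte name to match (default `"drug"`).
#' @return `rows` with a `conc` column (ng/mL); unmatched post-dose rows
#'   are dropped and counted in the `"dropped"` attribute.
#' @details The implicit zero applies to Day-1 pre-dose rows only: in a
#'   multiple-dose study a Day-10 pre-dose sample is a positive trough and
#'   must be matched against a measured concentration like any other row.
#' @export
pair_concentration <- function(rows, conc, analyte = "drug") {
  stopifnot(is.data.frame(rows), is.data.frame(conc))
  pk <- conc[conc$analyte == analyte, , drop = FALSE]
  if (is.null(pk$day)) pk$day <- 1
  key_pk <- paste(pk$subject_id, pk$treatment, pk$day, pk$time_h,
                  sep = "\r")
  key_rows <- paste(rows$subject_id, rows$treatment, rows$day, rows$time_h,
                    sep = "\r")
  idx <- match(key_rows, key_pk)
  rows$conc <- pk$conc[idx]
  rows$conc[rows$time_h <= 0 & rows$day == 1] <- 0
  matched <- !is.na(rows$conc)
  out <- rows[matched, , drop = FALSE]
  attr(out, "dropped") <- sum(!matched)
  if (any(!matched)) {
    warning(sum(!matched),
            " row(s) without a time-matched PK sample dropped",
            call. = FALSE)
  }
  reset_rows(out)
}

#' Full derivation chain from raw records to model-ready rows
#'
#' Convenience wrapper: [derive_qtcf()] then [baseline_adjust()], the
#' design-appropriate placebo correction, and [pair_concentration()].
#'
#' @param ecg ECG records data.frame.
#' @param conc PK records data.frame.
#' @param design `"crossover"` or `"parallel"`.
#' @param active Character vector of active treatment labels to keep
#'   (default: every non-placebo treatment present).
#' @param analyte PK analyte matched to the active rows.
#' @param placebo Placebo treatment label.
#' @param baseline_rule See [baseline_adjust()].
#' @return Model-ready rows (as [pair_concentration()]), with an
#'   `"accounting"` attribute listing rows in, rows out and drops per
#'   stage.
#' @export
derive_cqt_rows <- function(ecg, conc,
                            design = c("crossover", "parallel"),
                            active = NULL, analyte = "drug",
                            placebo = "placebo",
                            baseline_rule = c("day1", "daily")) {
  design <- match.arg(design)
  adj <- baseline_adjust(derive_qtcf(ecg), baseline_rule)
  corrected <- switch(design,
    crossover = placebo_correct_crossover(adj, placebo),
    parallel  = placebo_correct_parallel(adj, placebo))
  if (!is.null(active)) {
    corrected <- corrected[corrected$treatment %in% active, , drop = FALSE]
  }
  rows <- pair_concentration(corrected, conc, analyte)
  attr(rows, "accounting") <- list(
    n_ecg_in = nrow(ecg),
    n_baseline_excluded = attr(adj, "n_excluded"),
    n_unmatched_placebo = attr(corrected, "dropped"),
    n_unmatched_conc = attr(rows, "dropped"),
    n_rows_out = nrow(rows))
  rows
}
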