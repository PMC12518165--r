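## Tabular domain data: long-format ECG intervals and PK concentrations.
## Units are fixed: ms, hours, ng/mL. No auto-detection.

ECG_COLUMNS  <- c("subject_id", "treatment", "period", "day", "time_h",
                  "qt_ms", "rr_ms")
CONC_COLUMNS <- c("subject_id", "treatment", "period", "time_h",
                  "analyte", "conc")

#' Read long-format ECG interval data from CSV
#'
#' Reads one measured ECG timepoint per row. Required columns:
#' `subject_id`, `treatment`, `period`, `day`, `time_h`, `qt_ms`, `rr_ms`.
#' Rows with non-numeric or non-positive intervals, or missing identifiers,
#' are never silently dropped: they are collected into a rejection report
#' with a human-readable reason. Physiologically suspect rows with
#' `qt_ms >= rr_ms` are parsed but flagged (`flag_qt_ge_rr`), not rejected.
#'
#' @param path Path to a CSV file (UTF-8, one header row).
#' @return An object of class `cqt_read`: a list with elements
#'   `records` (accepted rows, a data.frame with an added logical
#'   `flag_qt_ge_rr` column), `rejected` (rejected raw rows with a `reason`
#'   column) and `n_input` (rows read). `nrow(records) + nrow(rejected)`
#'   always equals `n_input`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("subject_id,treatment,period,day,time_h,qt_ms,rr_ms",
#'              "S1,placebo,1,1,0,400,1000",
#'              "S1,placebo,1,1,2,NA,900"), f)
#' rd <- read_ecg_csv(f)
#' nrow(rd$records); rd$rejected$reason
#' @seealso [read_conc_csv()], [write_ecg_csv()]
#' @export
read_ecg_csv <- function(path) {
  raw <- read_study_csv(path, ECG_COLUMNS)
  reason <- character(nrow(raw))
  for (col in c("qt_ms", "rr_ms", "time_h", "period", "day")) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(num) & !is_blankish(raw[[col]])
    reason <- note_reason(reason, bad, paste0("non-numeric ", col))
    reason <- note_reason(reason, is_blankish(raw[[col]]),
                          paste0("missing ", col))
    raw[[col]] <- num
  }
  reason <- note_reason(reason, is_blankish(raw$subject_id),
                        "missing subject_id")
  reason <- note_reason(reason, is_blankish(raw$treatment),
                        "missing treatment")
  ok <- !nzchar(reason)
  reason <- note_reason(reason, ok & raw$qt_ms <= 0, "non-positive qt_ms")
  reason <- note_reason(reason, ok & raw$rr_ms <= 0, "non-positive rr_ms")
  ok <- !nzchar(reason)

  records <- raw[ok, , drop = FALSE]
  records$flag_qt_ge_rr <- records$qt_ms >= records$rr_ms
  rejected <- raw[!ok, , drop = FALSE]
  rejected$reason <- reason[!ok]
  check_unique_keys(records,
                    c("subject_id", "treatment", "period", "day", "time_h"),
                    "ECG")
  structure(list(records = reset_rows(records),
                 rejected = reset_rows(rejected),
                 n_input = nrow(raw)),
            class = "cqt_read")
}

#' Read long-format PK concentration data from CSV
#'
#' Required columns: `subject_id`, `treatment`, `period`, `time_h`,
#' `analyte`, `conc` (ng/mL). Optional columns: `day` (defaults to 1) and
#' `lloq_flag` (defaults to FALSE). Negative or non-numeric concentrations
#' are rejected with a reason; see [read_ecg_csv()] for the accounting
#' contract.
#'
#' @param path Path to a CSV file.
#' @return A `cqt_read` list with `records`, `rejected`, `n_input`.
#' @seealso [apply_lloq()]
#' @export
read_conc_csv <- function(path) {
  raw <- read_study_csv(path, CONC_COLUMNS)
  if (is.null(raw$day)) raw$day <- 1
  if (is.null(raw$lloq_flag)) raw$lloq_flag <- FALSE
  raw$lloq_flag <- as.logical(raw$lloq_flag)
  reason <- character(nrow(raw))
  for (col in c("conc", "time_h", "period", "day")) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(num) & !is_blankish(raw[[col]])
    reason <- note_reason(reason, bad, paste0("non-numeric ", col))
    reason <- note_reason(reason, is_blankish(raw[[col]]),
                          paste0("missing ", col))
    raw[[col]] <- num
  }
  reason <- note_reason(reason, is_blankish(raw$subject_id),
                        "missing subject_id")
  ok <- !nzchar(reason)
  reason <- note_reason(reason, ok & raw$conc < 0, "negative conc")
  ok <- !nzchar(reason)
  records <- raw[ok, , drop = FALSE]
  rejected <- raw[!ok, , drop = FALSE]
  rejected$reason <- reason[!ok]
  structure(list(records = reset_rows(records),
                 rejected = reset_rows(rejected),
                 n_input = nrow(raw)),
            class = "cqt_read")
}

#' @export
print.cqt_read <- function(x, ...) {
  cat("Study CSV read:", x$n_input, "rows;",
      nrow(x$records), "accepted,", nrow(x$rejected), "rejected\n")
  if (nrow(x$rejected) > 0) {
    tab <- table(x$rejected$reason)
    for (r in names(tab)) cat("  -", r, ":", tab[[r]], "\n")
  }
  invisible(x)
}

#' Write ECG or PK records back to CSV
#'
#' Numeric columns are written at full precision (15 significant digits),
#' so a write/read round trip reproduces identifiers bit-identically and
#' numerics to printed precision.
#'
#' @param records A data.frame of ECG (or PK) records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(records, path) {
  write_study_csv(records, path)
}

#' @rdname write_ecg_csv
#' @export
write_conc_csv <- function(records, path) {
  write_study_csv(records, path)
}

#' Apply a lower limit of quantification to PK records
#'
#' Concentrations below `lloq` are set to 0. Pre-dose records
#' (`time_h <= 0`) are zeroed silently (a single-dose period has no drug on
#' board before dosing); post-dose below-limit records are zeroed and
#' flagged via `lloq_flag` so that downstream summaries can count them.
#'
#' @param records PK records data.frame (see [read_conc_csv()]).
#' @param lloq Lower limit of quantification, ng/mL (> 0).
#' @return The records with `conc` and `lloq_flag` updated.
#' @examples
#' pk <- data.frame(subject_id = "S1", treatment = "drug", period = 1,
#'                  time_h = c(0, 2), analyte = "drug", conc = c(0.2, 0.4))
#' apply_lloq(pk, lloq = 0.5)
#' @export
apply_lloq <- function(records, lloq) {
  if (!is.numeric(lloq) || length(lloq) != 1L || !is.finite(lloq) ||
      lloq <= 0) {
    stop("`lloq` must be a single positive number (ng/mL)", call. = FALSE)
  }
  if (is.null(records$lloq_flag)) records$lloq_flag <- FALSE
  blq <- records$conc < lloq
  records$lloq_flag <- records$lloq_flag | (blq & records$time_h > 0)
  records$conc[blq] <- 0
  records
}

## ---- internal helpers -------------------------------------------------

read_study_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw
}

write_study_csv <- function(records, path) {
  out <- records
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

is_blankish <- function(x) {
  is.na(x) | (is.character(x) & !nzchar(trimws(as.character(x))))
}

note_reason <- function(reason, which, msg) {
  new <- which & !nzchar(reason)
  reason[new] <- msg
  reason
}

check_unique_keys <- function(df, keys, what) {
  if (nrow(df) == 0) return(invisible(TRUE))
  key <- do.call(paste, c(df[keys], sep = "\r"))
  if (anyDuplicated(key)) {
    warning(what, " data: ", sum(duplicated(key)),
            " duplicated (", paste(keys, collapse = ", "), ") key(s)",
            call. = FALSE)
  }
  invisible(TRUE)
}

reset_rows <- function(df) {
  rownames(df) <- NULL
  df
}
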