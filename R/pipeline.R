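## Pipeline orchestration: simulate -> derive -> fit -> diagnose ->
## report, with run manifests and a consolidated text report. These are
## the functions behind the thin command-line wrapper in inst/cli/.

#' Simulate a study and write its dataset to disk
#'
#' Writes `ecg.csv`, `pk.csv`, `truth.csv` and `manifest.json` into
#' `out_dir`.
#'
#' @param config A `study_config` (or path to a YAML/JSON config file).
#' @param out_dir Output directory (created if needed).
#' @param seed Seed forwarded to [simulate_study()].
#' @return The simulated `cqt_study`, invisibly.
#' @export
run_simulate <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_study_config(config)
  study <- simulate_study(config, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_ecg_csv(study$ecg, file.path(out_dir, "ecg.csv"))
  write_conc_csv(study$pk, file.path(out_dir, "pk.csv"))
  write_study_csv(study$truth, file.path(out_dir, "truth.csv"))
  manifest <- run_manifest(
    command = "simulate", seed = study$seed,
    paths = list(out_dir = out_dir,
                 files = c("ecg.csv", "pk.csv", "truth.csv")),
    config = list(design = study$config$design),
    accounting = list(n_ecg = nrow(study$ecg), n_pk = nrow(study$pk)))
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(study)
}

#' Run the complete concentration-QTc analysis
#'
#' Derives QTcF/ddQTcF, pairs concentrations, fits the mixed-effects
#' C-QTcF model to the pooled active arms (and, when present, to the
#' positive-control arm), runs the assumption diagnostics and NCA, and
#' issues the regulatory verdicts. Verdict outcomes are analysis results,
#' never errors; only unreadable inputs or an empty model frame fail.
#'
#' @param ecg ECG records: a data.frame or a CSV path
#'   (see [read_ecg_csv()]).
#' @param pk PK records: a data.frame or a CSV path.
#' @param design `"crossover"` or `"parallel"`.
#' @param conc_of_interest Concentration(s) of interest, ng/mL; default:
#'   the per-dose geometric mean Cmax values observed in the PK data.
#' @param level Two-sided confidence level (default 0.90).
#' @param threshold_ms Exclusion threshold (default 10).
#' @param sensitivity_threshold_ms Assay-sensitivity threshold
#'   (default 5).
#' @param placebo,moxifloxacin Treatment labels.
#' @param baseline_rule See [baseline_adjust()].
#' @param out_dir Optional output directory for the report bundle
#'   (`derived_rows.csv`, `fit_active.json`, `fit_moxifloxacin.json`,
#'   `diagnostics.json`, `report.txt`, `manifest.json`).
#' @return An object of class `cqt_report`: fits, predictions, verdicts,
#'   diagnostics, NCA summaries, row accounting and the manifest.
#' @export
run_analyze <- function(ecg, pk, design = c("crossover", "parallel"),
                        conc_of_interest = NULL, level = 0.90,
                        threshold_ms = 10, sensitivity_threshold_ms = 5,
                        placebo = "placebo",
                        moxifloxacin = "moxifloxacin",
                        baseline_rule = c("day1", "daily"),
                        out_dir = NULL) {
  design <- match.arg(design)
  baseline_rule <- match.arg(baseline_rule)
  input_paths <- list()
  if (is.character(ecg)) {
    input_paths$ecg <- ecg
    ecg <- read_ecg_csv(ecg)$records
  }
  if (is.character(pk)) {
    input_paths$pk <- pk
    pk <- read_conc_csv(pk)$records
  }
  treatments <- unique(ecg$treatment)
  active <- setdiff(treatments, c(placebo, moxifloxacin))
  if (design == "crossover" && !placebo %in% treatments) {
    stop("crossover analysis requires a '", placebo, "' arm",
         call. = FALSE)
  }

  rows <- derive_cqt_rows(ecg, pk, design = design, active = active,
                          analyte = "drug", placebo = placebo,
                          baseline_rule = baseline_rule)
  if (nrow(rows) == 0) {
    acc <- attr(rows, "accounting")
    stop("derivation produced 0 model-ready rows (",
         acc$n_ecg_in, " ECG rows in; ", acc$n_baseline_excluded,
         " baseline-excluded; ", acc$n_unmatched_placebo,
         " placebo-unmatched; ", acc$n_unmatched_conc,
         " concentration-unmatched)", call. = FALSE)
  }
  fit_active <- fit_cqtc(rows, level = level)

  ## per-dose geometric mean Cmax from the PK data
  nca <- nca_by_subject(pk, analyte = "drug")
  gmean_by_trt <- vapply(split(nca$cmax, nca$treatment),
                         function(v) exp(mean(log(v))), 0)
  if (is.null(conc_of_interest)) conc_of_interest <- unname(gmean_by_trt)
  pred <- predict(fit_active, sort(unique(conc_of_interest)),
                  level = level)
  verdict_active <- assess_no_prolongation(fit_active,
                                           max(conc_of_interest),
                                           threshold_ms, level)

  fit_moxi <- NULL
  verdict_moxi <- NULL
  pred_moxi <- NULL
  if (moxifloxacin %in% treatments && design == "crossover") {
    rows_moxi <- derive_cqt_rows(ecg, pk, design = design,
                                 active = moxifloxacin,
                                 analyte = "moxifloxacin",
                                 placebo = placebo,
                                 baseline_rule = baseline_rule)
    if (nrow(rows_moxi) > 0) {
      fit_moxi <- fit_cqtc(rows_moxi, level = level)
      nca_moxi <- nca_by_subject(pk, analyte = "moxifloxacin")
      gmean_cmax_moxi <- exp(mean(log(nca_moxi$cmax)))
      pred_moxi <- predict(fit_moxi, gmean_cmax_moxi, level = level)
      verdict_moxi <- assess_assay_sensitivity(
        fit_moxi, gmean_cmax_moxi, sensitivity_threshold_ms, level)
    }
  }

  diagnostics <- cqt_diagnostics(rows, level = level)
  accounting <- attr(rows, "accounting")
  manifest <- run_manifest(
    command = "analyze", seed = NA,
    paths = c(input_paths, list(out_dir = out_dir)),
    config = list(design = design, level = level,
                  threshold_ms = threshold_ms,
                  sensitivity_threshold_ms = sensitivity_threshold_ms,
                  baseline_rule = baseline_rule),
    accounting = accounting)

  report <- structure(list(
    fit_active = fit_active, fit_moxifloxacin = fit_moxi,
    predictions = pred, predictions_moxifloxacin = pred_moxi,
    verdict_no_prolongation = verdict_active,
    verdict_assay_sensitivity = verdict_moxi,
    diagnostics = diagnostics, nca = nca,
    gmean_cmax = gmean_by_trt, rows = rows,
    accounting = accounting, manifest = manifest),
    class = "cqt_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_study_csv(rows, file.path(out_dir, "derived_rows.csv"))
    jsonlite::write_json(fit_json(fit_active),
                         file.path(out_dir, "fit_active.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(fit_moxi)) {
      jsonlite::write_json(fit_json(fit_moxi),
                           file.path(out_dir, "fit_moxifloxacin.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    jsonlite::write_json(diagnostics_json(diagnostics),
                         file.path(out_dir, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "report.txt"))
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  report
}

#' @export
print.cqt_report <- function(x, ...) {
  cat("==== Concentration-QTcF analysis report ====\n\n")
  cat("-- Exposure-response model (active treatment) --\n")
  print(summary(x$fit_active))
  cat("\nMean ddQTcF at the concentrations of interest:\n")
  print(x$predictions)
  cat("\n")
  print(x$verdict_no_prolongation)
  if (!is.null(x$fit_moxifloxacin)) {
    cat("\n-- Assay sensitivity (positive control) --\n")
    print(summary(x$fit_moxifloxacin))
    if (!is.null(x$predictions_moxifloxacin)) {
      cat("\nMean ddQTcF at the positive control's gmean Cmax:\n")
      print(x$predictions_moxifloxacin)
    }
    cat("\n")
    print(x$verdict_assay_sensitivity)
  }
  cat("\n-- Diagnostics --\n")
  print(x$diagnostics)
  cat("\n-- PK geometric mean Cmax by treatment (ng/mL) --\n")
  print(round(x$gmean_cmax, 1))
  acc <- x$accounting
  cat(sprintf(
    "\nRow accounting: %d ECG rows in -> %d model rows (%d baseline-excluded, %d placebo-unmatched, %d concentration-unmatched)\n",
    acc$n_ecg_in, acc$n_rows_out, acc$n_baseline_excluded,
    acc$n_unmatched_placebo, acc$n_unmatched_conc))
  invisible(x)
}

#' Serialisable summary of a fitted C-QTc model
#'
#' @param fit A `cqt_fit`.
#' @return A plain list (estimates, covariances, criterion, dimensions)
#'   suitable for `jsonlite::write_json()`. Deterministic for a given
#'   fit: no timestamps.
#' @export
fit_json <- function(fit) {
  list(coefficients = as.list(fit$coefficients),
       vcov = unclass(fit$vcov),
       omega = if (!is.null(fit$omega)) unclass(fit$omega),
       sigma2 = fit$sigma2,
       reml_criterion = fit$logLik,
       baseline_centre = fit$baseline_centre,
       df = fit$df, level = fit$level, random = fit$random,
       n_obs = fit$n_obs, n_subjects = fit$n_subjects,
       convergence = fit$convergence)
}

diagnostics_json <- function(d) {
  list(
    hr = if (!is.null(d$hr)) {
      list(max_abs_bpm = d$hr$max_abs_bpm,
           threshold_bpm = d$hr$threshold_bpm, passed = d$hr$passed)
    },
    hysteresis = list(t_peak_conc_h = d$hysteresis$t_peak_conc_h,
                      t_peak_ddqtcf_h = d$hysteresis$t_peak_ddqtcf_h,
                      lag_h = d$hysteresis$lag_h,
                      flagged = d$hysteresis$flagged),
    linearity = list(max_discrepancy_ms = d$linearity$max_discrepancy_ms,
                     residual_sd_ms = d$linearity$residual_sd_ms,
                     flagged = d$linearity$flagged),
    deciles = d$deciles)
}

run_manifest <- function(command, seed, paths, config, accounting) {
  list(command = command,
       package_version = as.character(utils::packageVersion("cqtr")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed, paths = paths, config = config,
       accounting = accounting)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
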