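## Study simulator: TQT 4x4 crossover and MAD parallel-group designs with
## known ground truth, built so that re-derivation through the analysis
## chain recovers the generated quantities exactly when noise is zero.
##
## Generating model for corrected QTcF at time t (active arms):
##   QTcF_i(t) = B_i + diurnal(t) + b0i + (slope + b1i) * C_i(t) + e
## with the placebo arm sharing B_i and diurnal(t), so time-matched
## correction cancels the diurnal term exactly in expectation. QT is
## back-computed from QTcF and a simulated RR through the Fridericia
## inverse, so derive_qtcf() recovers QTcF to numerical precision.

#' Reference configuration of a 4x4 crossover TQT study
#'
#' Defaults emulate a thorough QT study in 28 healthy adults: four
#' treatment sequences (active low dose, active high dose, placebo,
#' moxifloxacin 400 mg as positive control; a balanced 4x4 Latin square,
#' 7 subjects per sequence), single doses, ECG and PK sampling pre-dose
#' and 0.5-48 h post-dose. Drug PK is a two-compartment oral model
#' (biphasic decline, terminal half-life about 34 h, tmax 0.5-4 h, gmean
#' Cmax about 220/440 ng/mL at 16/32 mg, AUCinf about D/CL = 5000/10000
#' h*ng/mL) with log-normal inter-individual variability (CV 25% on CL/F
#' and V1, 20% on ka). QTc: baseline mean 410 ms (SD 12 between
#' subjects), two-harmonic cosine diurnal rhythm (24 h and 12 h periods,
#' amplitudes 5 and 2 ms), concentration slope 0.0054 ms per ng/mL,
#' random intercept/slope covariance with SDs 2 ms and 0.0015 ms per
#' ng/mL (correlation -0.2), residual SD 6 ms.
#'
#' @param n_subjects Number of subjects (multiple of 4 for balance).
#' @param doses_mg Named numeric vector mapping active treatment labels
#'   to doses.
#' @param sampling_times_h Post-dose ECG/PK nominal grid, hours.
#' @param predose_times_h Pre-dose ECG baseline window replicates
#'   (<= 0), hours.
#' @param pk,qtc,moxifloxacin,rr Component parameter lists; any element
#'   supplied overrides the reference default.
#' @param seed Default seed used by [simulate_study()].
#' @return A `study_config` list.
#' @export
tqt_config <- function(n_subjects = 28,
                       doses_mg = c(active_16mg = 16,
                                    active_32mg = 32),
                       sampling_times_h = c(0.5, 1, 1.5, 2, 3, 4, 6, 8,
                                            12, 24, 48),
                       predose_times_h = c(-0.3, -0.1),
                       pk = list(), qtc = list(), moxifloxacin = list(),
                       rr = list(), seed = NULL) {
  pk <- utils::modifyList(reference_pk(), pk)
  qtc <- utils::modifyList(reference_qtc(slope = 0.0054), qtc)
  moxifloxacin <- utils::modifyList(reference_moxi(), moxifloxacin)
  rr <- utils::modifyList(reference_rr(), rr)
  active <- names(doses_mg)
  sequences <- default_sequences(active)
  cfg <- list(design = "crossover4x4", n_subjects = n_subjects,
              doses_mg = doses_mg, sequences = sequences,
              sampling_times_h = sampling_times_h,
              predose_times_h = predose_times_h,
              pk = pk, qtc = qtc, moxifloxacin = moxifloxacin, rr = rr,
              seed = seed)
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

#' Reference configuration of a parallel-group MAD study
#'
#' Defaults emulate a 10-day once-daily multiple-ascending-dose study:
#' five cohorts randomised 3:1 active:placebo (doses 2.5, 5, 1.5, 2.5
#' and 0.5 mg; 42 active and 14 placebo subjects in total), ECG and PK
#' sampled on Days 1 and 10 (pre-dose and 0.5-24 h post-dose),
#' concentrations by superposition of the single-dose two-compartment
#' profile (steady-state accumulation ratio about 2.2 at the reference
#' half-life). The concentration slope default is -0.15 ms per ng/mL at
#' these low-dose (tens of ng/mL) exposures.
#'
#' @param cohorts Data.frame with columns `dose_mg`, `n_active`,
#'   `n_placebo`.
#' @param n_days Days of once-daily dosing.
#' @param tau_h Dosing interval, hours.
#' @param sample_days Days on which ECG/PK are collected.
#' @param sampling_times_h Post-dose nominal grid within a sampling day.
#' @param predose_times_h Day-1 pre-dose baseline replicates (<= 0).
#' @param pk,qtc,rr,seed As [tqt_config()].
#' @return A `study_config` list.
#' @export
mad_config <- function(cohorts = data.frame(
                         dose_mg = c(2.5, 5, 1.5, 2.5, 0.5),
                         n_active = c(9, 9, 9, 6, 9),
                         n_placebo = c(3, 3, 3, 2, 3)),
                       n_days = 10, tau_h = 24, sample_days = c(1, 10),
                       sampling_times_h = c(0.5, 1, 2, 3, 4, 6, 8, 12, 24),
                       predose_times_h = c(-0.3, -0.1),
                       pk = list(), qtc = list(), rr = list(),
                       seed = NULL) {
  pk <- utils::modifyList(reference_pk(), pk)
  qtc <- utils::modifyList(reference_qtc(slope = -0.15), qtc)
  rr <- utils::modifyList(reference_rr(), rr)
  cfg <- list(design = "parallel_mad", cohorts = cohorts,
              n_days = n_days, tau_h = tau_h, sample_days = sample_days,
              sampling_times_h = sampling_times_h,
              predose_times_h = predose_times_h,
              pk = pk, qtc = qtc, rr = rr, seed = seed)
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

#' Read a study configuration from YAML or JSON
#'
#' The file holds the arguments of [tqt_config()] / [mad_config()] plus a
#' `design` field choosing between them; omitted fields keep their
#' reference defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_study_config(lst)
}

#' @rdname read_study_config
#' @param x A plain list of configuration fields.
#' @export
as_study_config <- function(x) {
  stopifnot(is.list(x))
  design <- x$design %||% "crossover4x4"
  x$design <- NULL
  if (!is.null(x$doses_mg)) x$doses_mg <- unlist(x$doses_mg)
  if (!is.null(x$cohorts)) x$cohorts <- as.data.frame(x$cohorts)
  if (!is.null(x$qtc$omega)) {
    x$qtc$omega <- matrix(unlist(x$qtc$omega), 2, 2)
  }
  maker <- switch(design,
                  crossover4x4 = tqt_config,
                  parallel_mad = mad_config,
                  stop("unknown design: ", design, call. = FALSE))
  do.call(maker, x)
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration:", x$design, "\n")
  if (x$design == "crossover4x4") {
    cat(sprintf("  %d subjects, doses %s mg + placebo + moxifloxacin\n",
                x$n_subjects, paste(x$doses_mg, collapse = "/")))
  } else {
    cat(sprintf("  %d cohorts, %d active + %d placebo subjects, %d days\n",
                nrow(x$cohorts), sum(x$cohorts$n_active),
                sum(x$cohorts$n_placebo), x$n_days))
  }
  cat(sprintf("  qtc slope %g ms per ng/mL, residual SD %g ms\n",
              x$qtc$slope_ms_per_ng_ml, x$qtc$residual_sd_ms))
  invisible(x)
}

#' Closed-form oral two-compartment concentration profile
#'
#' Analytic three-exponential solution for a single oral dose with
#' first-order absorption and two-compartment disposition; reduces to the
#' one-compartment closed form when `q = 0` (or `v2` absent). Coincident
#' rate constants are handled by the documented limiting form (exact
#' `k*t*exp(-k*t)` limit in one compartment; an infinitesimal relative
#' perturbation of `ka` in two compartments).
#'
#' @param pk List with `ka` (1/h), `cl_f` (L/h), `v1_l` (L) and,
#'   optionally, `v2_l` (L) and `q_l_h` (L/h).
#' @param dose_mg Dose, mg.
#' @param times_h Times, hours (concentration is 0 at `t <= 0`).
#' @return Concentrations, ng/mL.
#' @examples
#' cfg <- tqt_config()
#' simulate_pk_profile(cfg$pk, 32, c(0, 1, 2, 4, 24, 48))
#' @export
simulate_pk_profile <- function(pk, dose_mg, times_h) {
  stopifnot(pk$ka > 0, pk$cl_f > 0, pk$v1_l > 0, dose_mg > 0)
  t <- pmax(times_h, 0)
  amt <- 1000 * dose_mg / pk$v1_l            # mg -> ng/mL scale
  ka <- pk$ka
  k10 <- pk$cl_f / pk$v1_l
  two_cpt <- !is.null(pk$v2_l) && !is.null(pk$q_l_h) && pk$q_l_h > 0
  if (!two_cpt) {
    conc <- if (abs(ka - k10) < 1e-9 * ka) {
      amt * k10 * t * exp(-k10 * t)
    } else {
      amt * ka / (ka - k10) * (exp(-k10 * t) - exp(-ka * t))
    }
  } else {
    k12 <- pk$q_l_h / pk$v1_l
    k21 <- pk$q_l_h / pk$v2_l
    s <- k10 + k12 + k21
    disc <- sqrt(s^2 - 4 * k10 * k21)
    alpha <- (s + disc) / 2
    beta <- (s - disc) / 2
    if (min(abs(ka - alpha), abs(ka - beta)) < 1e-9 * ka ||
        abs(alpha - beta) < 1e-12 * alpha) {
      ka <- ka * (1 + 1e-6)
    }
    A <- (k21 - alpha) / ((ka - alpha) * (beta - alpha))
    B <- (k21 - beta) / ((ka - beta) * (alpha - beta))
    Cc <- (k21 - ka) / ((alpha - ka) * (beta - ka))
    conc <- amt * ka * (A * exp(-alpha * t) + B * exp(-beta * t) +
                          Cc * exp(-ka * t))
  }
  conc[times_h <= 0] <- 0
  pmax(conc, 0)
}

#' Simulate a complete study with known ground truth
#'
#' Generates the full long-format ECG and PK dataset for every arm
#' (including the positive control in the crossover design) together with
#' a truth table of the realised subject-level parameters. Deterministic
#' given the seed: per-subject substreams are derived from the global
#' seed, so the same seed reproduces the dataset bit-identically.
#'
#' @param config A `study_config` from [tqt_config()] or [mad_config()].
#' @param seed Integer seed (defaults to the config's; required in one of
#'   the two places).
#' @return An object of class `cqt_study`: a list with `ecg`, `pk`,
#'   `truth` data.frames, `design` (`"crossover"` or `"parallel"`),
#'   `config` and `seed`. `truth` carries the per-subject baselines, PK
#'   parameters and random effects; the generating fixed effects are in
#'   `attr(truth, "theta")`.
#' @examples
#' study <- simulate_study(tqt_config(), seed = 42)
#' head(study$ecg)
#' @export
simulate_study <- function(config, seed = NULL) {
  stopifnot(inherits(config, "study_config"))
  seed <- seed %||% config$seed
  if (is.null(seed)) stop("a seed is required", call. = FALSE)
  switch(config$design,
         crossover4x4 = simulate_crossover(config, seed),
         parallel_mad = simulate_mad(config, seed))
}

#' @export
print.cqt_study <- function(x, ...) {
  cat(sprintf("Simulated %s study (seed %d): %d ECG rows, %d PK rows, %d subjects\n",
              x$design, x$seed, nrow(x$ecg), nrow(x$pk),
              nrow(x$truth)))
  invisible(x)
}

## ---- reference parameter sets -----------------------------------------

reference_pk <- function() {
  list(ka = 1.2, cl_f = 3.2, v1_l = 55, v2_l = 60, q_l_h = 3,
       iiv_cv_percent = c(cl_f = 25, v1_l = 25, ka = 20))
}

reference_qtc <- function(slope) {
  list(baseline_mean_ms = 410, baseline_sd_ms = 12,
       diurnal_amplitude_ms = c(5, 2), diurnal_phase = c(0, 0),
       clock_offset_h = 8,
       slope_ms_per_ng_ml = slope,
       omega = matrix(c(2^2, -0.2 * 2 * 0.0015,
                        -0.2 * 2 * 0.0015, 0.0015^2), 2, 2),
       residual_sd_ms = 6,
       hr_effect_bpm = 0, hr_effect_from_day = 1)
}

reference_moxi <- function() {
  list(pk = list(ka = 1.4, cl_f = 12, v1_l = 135, v2_l = 40, q_l_h = 2,
                 iiv_cv_percent = c(cl_f = 20, v1_l = 20, ka = 20)),
       dose_mg = 400, slope_ms_per_ng_ml = 0.0044,
       treatment = "moxifloxacin")
}

reference_rr <- function() {
  list(mean_ms = 900, sd_between_ms = 50, sd_within_ms = 15)
}

default_sequences <- function(active) {
  ## the study's four sequences (A = low dose, B = high dose, C = placebo,
  ## D = positive control): a balanced 4x4 Latin square
  a <- active[1]; b <- active[2]
  rbind(c(a, b, "placebo", "moxifloxacin"),
        c(b, "moxifloxacin", a, "placebo"),
        c("placebo", a, "moxifloxacin", b),
        c("moxifloxacin", "placebo", b, a))
}

validate_study_config <- function(cfg) {
  with(cfg, {
    stopifnot(all(diff(sampling_times_h) > 0), all(sampling_times_h > 0),
              all(predose_times_h <= 0),
              qtc$residual_sd_ms >= 0, qtc$baseline_sd_ms >= 0,
              all(eigen(qtc$omega, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
  })
  if (cfg$design == "crossover4x4") {
    sq <- cfg$sequences
    if (!all(apply(sq, 1, function(r) !anyDuplicated(r))) ||
        !all(apply(sq, 2, function(c) !anyDuplicated(c)))) {
      stop("invalid sequence matrix: each treatment must appear once per ",
           "sequence and once per period", call. = FALSE)
    }
    if (cfg$n_subjects %% nrow(sq) != 0) {
      warning("n_subjects is not a multiple of the number of sequences; ",
              "the design is unbalanced", call. = FALSE)
    }
  } else {
    stopifnot(is.data.frame(cfg$cohorts),
              all(c("dose_mg", "n_active", "n_placebo") %in%
                    names(cfg$cohorts)),
              all(cfg$sample_days >= 1), all(cfg$sample_days <= cfg$n_days))
  }
  invisible(cfg)
}

## ---- internals ---------------------------------------------------------

subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + 7919 * i) %% (2^31 - 1)) + 1L
}

diurnal_qtc <- function(t_global, qtc) {
  a <- qtc$diurnal_amplitude_ms
  p <- qtc$diurnal_phase
  off <- qtc$clock_offset_h
  a[1] * cos(2 * pi * (t_global + off) / 24 + p[1]) +
    a[2] * cos(2 * pi * (t_global + off) / 12 + p[2])
}

draw_pk_params <- function(pk) {
  cv <- pk$iiv_cv_percent
  sdl <- sqrt(log(1 + (cv / 100)^2))
  out <- pk
  out$cl_f <- pk$cl_f * exp(stats::rnorm(1, 0, sdl[["cl_f"]]))
  out$v1_l <- pk$v1_l * exp(stats::rnorm(1, 0, sdl[["v1_l"]]))
  out$ka <- pk$ka * exp(stats::rnorm(1, 0, sdl[["ka"]]))
  out
}

## One arm's ECG records for one subject. eta applies post-dose only (the
## treatment-induced shift the corrected analysis sees as its random
## intercept); baseline and diurnal are shared across arms.
subject_arm_ecg <- function(subject_id, treatment, period, day, times_h,
                            t_global, conc, baseline, eta, slope, qtc,
                            rr_mean, rr, hr_shift = 0) {
  n <- length(times_h)
  ## the treatment shift and concentration effect act whenever drug can be
  ## on board: post-dose, or at a multiple-dose pre-dose trough (conc > 0)
  on_drug <- times_h > 0 | conc > 0
  qtcf <- baseline + diurnal_qtc(t_global, qtc) +
    ifelse(on_drug, eta[1] + (slope + eta[2]) * conc, 0) +
    stats::rnorm(n, 0, qtc$residual_sd_ms)
  rr_ms <- rr_mean + stats::rnorm(n, 0, rr$sd_within_ms)
  if (hr_shift != 0) {
    post <- times_h > 0
    rr_ms[post] <- 60000 / (60000 / rr_ms[post] + hr_shift)
  }
  qt_ms <- qtcf * (rr_ms / 1000)^(1 / 3)
  data.frame(subject_id = subject_id, treatment = treatment,
             period = period, day = day, time_h = times_h,
             qt_ms = qt_ms, rr_ms = rr_ms)
}

simulate_crossover <- function(cfg, seed) {
  n <- cfg$n_subjects
  seqs <- cfg$sequences
  times <- c(cfg$predose_times_h, cfg$sampling_times_h)
  pk_times <- c(0, cfg$sampling_times_h)
  ecg_list <- vector("list", n * 4)
  pk_list <- list()
  truth_list <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subject_seed(seed, i))
    sid <- sprintf("S%03d", i)
    seq_i <- ((i - 1) %% nrow(seqs)) + 1
    baseline <- stats::rnorm(1, cfg$qtc$baseline_mean_ms,
                             cfg$qtc$baseline_sd_ms)
    rr_mean <- stats::rnorm(1, cfg$rr$mean_ms, cfg$rr$sd_between_ms)
    eta_drug <- drop(rmvnorm_chol(1, cfg$qtc$omega))
    eta_moxi <- drop(rmvnorm_chol(1, cfg$qtc$omega))
    pk_i <- draw_pk_params(cfg$pk)
    pk_moxi_i <- draw_pk_params(cfg$moxifloxacin$pk)
    for (p in seq_len(ncol(seqs))) {
      trt <- seqs[seq_i, p]
      if (trt == "placebo") {
        conc <- rep(0, length(times))
        eta <- c(0, 0)
        slope <- 0
      } else if (trt == cfg$moxifloxacin$treatment) {
        conc <- simulate_pk_profile(pk_moxi_i, cfg$moxifloxacin$dose_mg,
                                    times)
        eta <- eta_moxi
        slope <- cfg$moxifloxacin$slope_ms_per_ng_ml
        pk_conc <- simulate_pk_profile(pk_moxi_i,
                                       cfg$moxifloxacin$dose_mg, pk_times)
        pk_list[[length(pk_list) + 1]] <- data.frame(
          subject_id = sid, treatment = trt, period = p, day = 1,
          time_h = pk_times, analyte = "moxifloxacin", conc = pk_conc)
      } else {
        dose <- cfg$doses_mg[[trt]]
        conc <- simulate_pk_profile(pk_i, dose, times)
        eta <- eta_drug
        slope <- cfg$qtc$slope_ms_per_ng_ml
        pk_list[[length(pk_list) + 1]] <- data.frame(
          subject_id = sid, treatment = trt, period = p, day = 1,
          time_h = pk_times, analyte = "drug",
          conc = simulate_pk_profile(pk_i, dose, pk_times))
      }
      ecg_list[[(i - 1) * 4 + p]] <- subject_arm_ecg(
        sid, trt, p, 1, times, times, conc, baseline, eta, slope,
        cfg$qtc, rr_mean, cfg$rr)
    }
    truth_list[[i]] <- data.frame(
      subject_id = sid, sequence = seq_i, baseline_qtcf_ms = baseline,
      rr_mean_ms = rr_mean, cl_f = pk_i$cl_f, v1_l = pk_i$v1_l,
      ka = pk_i$ka, eta0 = eta_drug[1], eta1 = eta_drug[2],
      eta0_moxi = eta_moxi[1], eta1_moxi = eta_moxi[2])
  }
  truth <- do.call(rbind, truth_list)
  attr(truth, "theta") <- c(
    theta0 = 0, slope = cfg$qtc$slope_ms_per_ng_ml,
    slope_moxi = cfg$moxifloxacin$slope_ms_per_ng_ml)
  structure(list(ecg = do.call(rbind, ecg_list),
                 pk = do.call(rbind, pk_list),
                 truth = truth, design = "crossover",
                 config = cfg, seed = seed),
            class = "cqt_study")
}

simulate_mad <- function(cfg, seed) {
  cohorts <- cfg$cohorts
  dose_times <- (seq_len(cfg$n_days) - 1) * cfg$tau_h
  ecg_list <- list()
  pk_list <- list()
  truth_list <- list()
  i <- 0
  for (k in seq_len(nrow(cohorts))) {
    arms <- c(rep("active", cohorts$n_active[k]),
              rep("placebo", cohorts$n_placebo[k]))
    dose <- cohorts$dose_mg[k]
    trt_active <- sprintf("dose_%gmg", dose)
    for (a in arms) {
      i <- i + 1
      set.seed(subject_seed(seed, i))
      sid <- sprintf("S%03d", i)
      baseline <- stats::rnorm(1, cfg$qtc$baseline_mean_ms,
                               cfg$qtc$baseline_sd_ms)
      rr_mean <- stats::rnorm(1, cfg$rr$mean_ms, cfg$rr$sd_between_ms)
      eta <- drop(rmvnorm_chol(1, cfg$qtc$omega))
      pk_i <- draw_pk_params(cfg$pk)
      trt <- if (a == "active") trt_active else "placebo"
      for (d in cfg$sample_days) {
        times <- if (d == 1) {
          c(cfg$predose_times_h, cfg$sampling_times_h)
        } else {
          c(0, cfg$sampling_times_h)
        }
        t_global <- (d - 1) * cfg$tau_h + times
        conc <- if (a == "active") {
          superpose_profile(pk_i, dose, dose_times, t_global)
        } else {
          rep(0, length(times))
        }
        hr_shift <- if (cfg$qtc$hr_effect_bpm != 0 && a == "active" &&
                          d >= cfg$qtc$hr_effect_from_day) {
          cfg$qtc$hr_effect_bpm
        } else 0
        ecg_list[[length(ecg_list) + 1]] <- subject_arm_ecg(
          sid, trt, 1, d, times, t_global, conc, baseline,
          if (a == "active") eta else c(0, 0),
          if (a == "active") cfg$qtc$slope_ms_per_ng_ml else 0,
          cfg$qtc, rr_mean, cfg$rr, hr_shift)
        if (a == "active") {
          pk_t <- if (d == 1) c(0, cfg$sampling_times_h) else times
          pk_list[[length(pk_list) + 1]] <- data.frame(
            subject_id = sid, treatment = trt, period = 1, day = d,
            time_h = pk_t, analyte = "drug",
            conc = superpose_profile(pk_i, dose, dose_times,
                                     (d - 1) * cfg$tau_h + pk_t))
        }
      }
      truth_list[[i]] <- data.frame(
        subject_id = sid, cohort = k, treatment = trt,
        dose_mg = if (a == "active") dose else 0,
        baseline_qtcf_ms = baseline, rr_mean_ms = rr_mean,
        cl_f = pk_i$cl_f, v1_l = pk_i$v1_l, ka = pk_i$ka,
        eta0 = if (a == "active") eta[1] else 0,
        eta1 = if (a == "active") eta[2] else 0)
    }
  }
  truth <- do.call(rbind, truth_list)
  attr(truth, "theta") <- c(theta0 = 0,
                            slope = cfg$qtc$slope_ms_per_ng_ml)
  structure(list(ecg = do.call(rbind, ecg_list),
                 pk = do.call(rbind, pk_list),
                 truth = truth, design = "parallel",
                 config = cfg, seed = seed),
            class = "cqt_study")
}

superpose_profile <- function(pk, dose_mg, dose_times, t_global) {
  out <- numeric(length(t_global))
  for (td in dose_times) {
    rel <- t_global - td
    if (any(rel > 0)) out <- out + simulate_pk_profile(pk, dose_mg, rel)
  }
  out
}
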