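## REML estimation of the linear mixed-effects C-QTcF model.
##
## Model, observation j of subject i:
##   ddqtcf_ij = (th0 + b0i) + (th1 + b1i) * C_ij + th2 * (B_i - Bbar) + e_ij
##   (b0i, b1i) ~ N(0, Omega) unstructured, e_ij ~ N(0, sigma2).
##
## Estimation: sigma2 is profiled out of the restricted likelihood; the
## scaled covariance Psi = Omega / sigma2 is parameterised by the
## log-Cholesky factor (guaranteeing positive semi-definiteness) and
## maximised numerically from fixed deterministic starts; fixed effects are
## the profiled generalized-least-squares solution. Per-subject algebra
## uses the Woodbury identity on cached cross-products, so each criterion
## evaluation costs O(q^3) per subject (q = number of random effects).

#' Low-level REML fit of a linear mixed model with subject-level effects
#'
#' The computational engine behind [fit_cqtc()], exposed so that simple
#' layouts (e.g. a balanced one-way random-intercept design) can be fitted
#' and checked against closed-form estimators.
#'
#' @param y Numeric response vector.
#' @param X Fixed-effects design matrix (rows match `y`).
#' @param subject Grouping factor (one level per subject).
#' @param z Numeric covariate carrying the random slope (required for
#'   `random = "intercept_slope"`).
#' @param random `"intercept_slope"` (random intercept and slope on `z`,
#'   unstructured 2x2 covariance), `"intercept"`, or `"none"` (ordinary
#'   least squares; the REML residual variance is the residual mean
#'   square).
#' @param control List of optimizer settings: `maxit` (default 2000),
#'   `reltol` (default 1e-12).
#' @return A list with elements `coefficients`, `vcov` (fixed-effect
#'   covariance from the GLS information), `omega` (random-effect
#'   covariance, `sigma2 * Psi`), `psi`, `sigma2`, `logLik` (attained
#'   restricted log-likelihood), `n`, `p`, `n_subjects`, `fitted`
#'   (population level), `residuals` (marginal), `ranef` (per-subject
#'   BLUPs), `convergence` and `start_used`.
#' @seealso [fit_cqtc()]
#' @export
lmm_reml <- function(y, X, subject, z = NULL,
                     random = c("intercept_slope", "intercept", "none"),
                     control = list()) {
  random <- match.arg(random)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, length(subject) == n)
  if (any(!is.finite(y)) || any(!is.finite(X))) {
    stop("non-finite values in the model frame", call. = FALSE)
  }
  if (qr(X)$rank < p) {
    stop("singular fixed-effect design: columns of X are linearly ",
         "dependent (e.g. all concentrations equal)", call. = FALSE)
  }
  subject <- factor(subject)
  maxit <- control$maxit %||% 2000
  reltol <- control$reltol %||% 1e-12

  q <- switch(random, intercept_slope = 2L, intercept = 1L, none = 0L)
  if (q == 2L && is.null(z)) {
    stop("`z` is required for a random slope", call. = FALSE)
  }
  Z <- switch(random,
              intercept_slope = cbind(1, as.numeric(z)),
              intercept = matrix(1, n, 1),
              none = NULL)

  idx <- split(seq_len(n), subject)
  n_subjects <- length(idx)
  if (q == 0L) {
    qrx <- qr(X)
    beta <- qr.coef(qrx, y)
    fitted <- drop(X %*% beta)
    res <- y - fitted
    sigma2 <- sum(res^2) / (n - p)
    XtX <- crossprod(X)
    logLik <- -0.5 * (log(det(XtX)) +
                        (n - p) * (1 + log(2 * pi * sigma2)))
    return(list(coefficients = stats::setNames(drop(beta), colnames(X)),
                vcov = sigma2 * solve(XtX), omega = NULL,
                psi = NULL, sigma2 = sigma2, logLik = logLik,
                n = n, p = p, n_subjects = n_subjects,
                fitted = fitted, residuals = res,
                ranef = NULL, convergence = 0L, start_used = NA_integer_))
  }

  ## cache per-subject cross products
  pieces <- lapply(idx, function(ii) {
    Zi <- Z[ii, , drop = FALSE]
    Xi <- X[ii, , drop = FALSE]
    yi <- y[ii]
    list(ZtZ = crossprod(Zi), ZtX = crossprod(Zi, Xi),
         Zty = drop(crossprod(Zi, yi)))
  })
  XtX_tot <- crossprod(X)
  Xty_tot <- drop(crossprod(X, y))
  yty_tot <- sum(y^2)
  Iq <- diag(q)

  profile_at <- function(Psi, want = "crit") {
    XtWX <- XtX_tot
    XtWy <- Xty_tot
    yWy <- yty_tot
    logdetW <- 0
    A_list <- vector("list", length(pieces))
    for (k in seq_along(pieces)) {
      pc <- pieces[[k]]
      M <- Iq + pc$ZtZ %*% Psi
      dM <- det(M)
      if (!is.finite(dM) || dM <= 0) return(NULL)
      A <- Psi %*% solve(M)
      A <- (A + t(A)) / 2
      XtWX <- XtWX - t(pc$ZtX) %*% A %*% pc$ZtX
      XtWy <- XtWy - drop(t(pc$ZtX) %*% A %*% pc$Zty)
      yWy <- yWy - drop(t(pc$Zty) %*% A %*% pc$Zty)
      logdetW <- logdetW + log(dM)
      if (want == "full") A_list[[k]] <- A
    }
    dX <- det(XtWX)
    if (!is.finite(dX) || dX <= 0) return(NULL)
    beta <- solve(XtWX, XtWy)
    quad <- max(yWy - sum(beta * XtWy), 1e-300)
    sigma2 <- quad / (n - p)
    logLik <- -0.5 * (logdetW + log(dX) +
                        (n - p) * (1 + log(2 * pi * sigma2)))
    if (want == "crit") return(logLik)
    list(beta = beta, sigma2 = sigma2, logLik = logLik,
         XtWX = XtWX, A_list = A_list)
  }

  psi_from_par <- function(par) {
    if (q == 1L) {
      matrix(exp(2 * par), 1, 1)
    } else {
      L <- matrix(c(exp(par[1]), par[2], 0, exp(par[3])), 2, 2)
      tcrossprod(L)
    }
  }
  negcrit <- function(par) {
    val <- profile_at(psi_from_par(par), "crit")
    if (is.null(val) || !is.finite(val)) return(1e10)
    -val
  }

  ## fixed deterministic starts: Psi = 0.1 I (Omega = 0.1 var(y) I at
  ## sigma2 = var(y)), then Psi = I and Psi = 0.01 I
  starts <- if (q == 1L) {
    list(0.5 * log(0.1), 0, 0.5 * log(0.01))
  } else {
    list(c(0.5 * log(0.1), 0, 0.5 * log(0.1)),
         c(0, 0, 0),
         c(0.5 * log(0.01), 0, 0.5 * log(0.01)))
  }
  best <- NULL
  best_val <- Inf
  best_start <- NA_integer_
  best_conv <- NA_integer_
  for (s in seq_along(starts)) {
    fit_s <- if (q == 1L) {
      stats::optim(starts[[s]], negcrit, method = "Brent",
                   lower = -15, upper = 8,
                   control = list(maxit = maxit, reltol = reltol))
    } else {
      stats::optim(starts[[s]], negcrit, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol))
    }
    if (fit_s$value < best_val - 1e-12) {
      best <- fit_s
      best_val <- fit_s$value
      best_start <- s
      best_conv <- fit_s$convergence
    }
  }
  if (is.null(best) || !is.finite(best_val) || best_val >= 1e10) {
    stop("REML estimation failed: restricted likelihood not finite at ",
         "any start", call. = FALSE)
  }
  if (best_conv != 0L) {
    warning("REML optimizer did not report convergence (code ", best_conv,
            ", ", best$counts[["function"]], " evaluations); estimates ",
            "are the best criterion value reached", call. = FALSE)
  }

  Psi <- psi_from_par(best$par)
  prof <- profile_at(Psi, "full")
  sigma2 <- prof$sigma2
  beta <- stats::setNames(drop(prof$beta), colnames(X))
  fitted <- drop(X %*% prof$beta)
  res <- y - fitted

  ## per-subject BLUPs: b_i = Psi Z_i' W_i^{-1} r_i
  ranef <- matrix(NA_real_, n_subjects, q,
                  dimnames = list(names(idx), NULL))
  for (k in seq_along(pieces)) {
    pc <- pieces[[k]]
    Ztr <- pc$Zty - drop(pc$ZtX %*% prof$beta)
    ZtWr <- Ztr - drop(pc$ZtZ %*% prof$A_list[[k]] %*% Ztr)
    ranef[k, ] <- drop(Psi %*% ZtWr)
  }

  list(coefficients = beta,
       vcov = sigma2 * solve(prof$XtWX),
       omega = sigma2 * Psi,
       psi = Psi,
       sigma2 = sigma2,
       logLik = prof$logLik,
       n = n, p = p, n_subjects = n_subjects,
       fitted = fitted, residuals = res,
       ranef = ranef,
       convergence = best_conv, start_used = best_start)
}

#' Fit the linear mixed-effects concentration-QTc model by REML
#'
#' Fits the pre-specified exposure-response model for placebo-corrected,
#' baseline-adjusted QTcF:
#' \deqn{\Delta\Delta QTcF_{ij} = (\theta_0 + b_{0i}) +
#'   (\theta_1 + b_{1i}) C_{ij} + \theta_2 (B_i - \bar B) + e_{ij}}
#' with subject-level random intercept and concentration slope
#' \eqn{(b_{0i}, b_{1i}) \sim N(0, \Omega)} (unstructured) and residual
#' \eqn{e_{ij} \sim N(0, \sigma^2)}. Variance parameters are estimated by
#' REML over a log-Cholesky parameterisation (positive semi-definite by
#' construction) from fixed deterministic starts; fixed effects are the
#' profiled GLS solution, so the fit is deterministic given the data.
#'
#' Concentration is rescaled internally by its standard deviation for
#' numerical conditioning; all reported quantities are on the original
#' ms-per-ng/mL scale.
#'
#' @param data Data.frame of model-ready rows with columns `conc` (ng/mL),
#'   `ddqtcf_ms`, `subject_id`, and (if `baseline = TRUE`)
#'   `baseline_qtcf_ms`. The output of [derive_cqt_rows()] fits directly.
#' @param level Default two-sided confidence level carried by the fit
#'   (used by `predict`/`confint`), default 0.90.
#' @param random Random-effects structure: `"intercept_slope"` (default,
#'   the pre-specified model), `"intercept"`, or `"none"` (Omega
#'   constrained to 0; fixed effects equal ordinary least squares).
#' @param baseline Include the centred baseline QTcF covariate
#'   (default `TRUE`).
#' @param baseline_centre Centring constant \eqn{\bar B} in ms; default:
#'   mean of the subject-level baselines over subjects contributing rows.
#'   Changing the centre shifts the intercept by `theta2 * delta` and
#'   leaves slope and baseline coefficients unchanged.
#' @param control Optimizer control passed to [lmm_reml()].
#' @return An object of class `cqt_fit` with components `coefficients`
#'   (`(Intercept)`, `slope`, `baseline`), `vcov`, `omega`, `sigma2`,
#'   `logLik` (restricted log-likelihood), `df` (t degrees of freedom,
#'   `n_subjects - p`), `baseline_centre`, `n_subjects`, `n_obs`, `level`,
#'   `data`, `fitted`, `residuals`, `ranef`, `convergence`.
#' @examples
#' set.seed(1)
#' n <- 12
#' rows <- data.frame(
#'   subject_id = rep(sprintf("S%02d", 1:n), each = 6),
#'   conc = rep(c(0, 50, 150, 300, 450, 600), n),
#'   baseline_qtcf_ms = rep(rnorm(n, 410, 12), each = 6))
#' rows$ddqtcf_ms <- -2 + 0.005 * rows$conc +
#'   rep(rnorm(n, 0, 1.5), each = 6) + rnorm(nrow(rows), 0, 4)
#' fit <- fit_cqtc(rows)
#' coef(fit)
#' predict(fit, conc = c(86, 180.7))
#' @seealso [predict.cqt_fit()], [assess_no_prolongation()],
#'   [assess_assay_sensitivity()]
#' @export
fit_cqtc <- function(data, level = 0.90,
                     random = c("intercept_slope", "intercept", "none"),
                     baseline = TRUE, baseline_centre = NULL,
                     control = list()) {
  random <- match.arg(random)
  stopifnot(is.data.frame(data))
  need <- c("conc", "ddqtcf_ms", "subject_id",
            if (baseline) "baseline_qtcf_ms")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("model rows lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rows <- data[stats::complete.cases(data[need]), need, drop = FALSE]
  if (length(unique(rows$subject_id)) < 2L) {
    stop("at least 2 subjects are required", call. = FALSE)
  }
  if (length(unique(rows$conc)) < 2L) {
    stop("singular design: all concentrations are equal", call. = FALSE)
  }
  s <- stats::sd(rows$conc)
  conc_s <- rows$conc / s

  if (baseline) {
    sub_base <- tapply(rows$baseline_qtcf_ms, rows$subject_id,
                       function(b) b[1])
    if (is.null(baseline_centre)) baseline_centre <- mean(sub_base)
    bc <- rows$baseline_qtcf_ms - baseline_centre
    X <- cbind("(Intercept)" = 1, slope = conc_s, baseline = bc)
  } else {
    baseline_centre <- NA_real_
    X <- cbind("(Intercept)" = 1, slope = conc_s)
  }

  eng <- lmm_reml(rows$ddqtcf_ms, X, rows$subject_id, z = conc_s,
                  random = random, control = control)

  ## back-transform from scaled concentration
  D <- diag(c(1, 1 / s, if (baseline) 1))
  beta <- drop(D %*% eng$coefficients)
  names(beta) <- colnames(X)
  vc <- D %*% eng$vcov %*% D
  dimnames(vc) <- list(names(beta), names(beta))
  omega <- eng$omega
  if (!is.null(omega)) {
    Tm <- if (nrow(omega) == 2L) diag(c(1, 1 / s)) else diag(1)
    omega <- Tm %*% omega %*% Tm
    rn <- c("intercept", "slope")[seq_len(nrow(omega))]
    dimnames(omega) <- list(rn, rn)
  }
  ranef <- eng$ranef
  if (!is.null(ranef) && ncol(ranef) == 2L) ranef[, 2] <- ranef[, 2] / s

  structure(list(
    coefficients = beta,
    vcov = vc,
    omega = omega,
    sigma2 = eng$sigma2,
    ## the restricted likelihood depends on the fixed-effect basis; undo
    ## the internal concentration rescaling so the criterion refers to
    ## the model as stated (conc in ng/mL)
    logLik = eng$logLik - log(s),
    baseline_centre = baseline_centre,
    n_subjects = eng$n_subjects,
    n_obs = eng$n,
    df = eng$n_subjects - eng$p,
    level = level,
    random = random,
    conc_scale = s,
    data = rows,
    fitted = eng$fitted,
    residuals = eng$residuals,
    ranef = ranef,
    convergence = eng$convergence,
    start_used = eng$start_used,
    call = match.call()),
    class = "cqt_fit")
}

#' Build a `cqt_fit` from published fixed-effect estimates
#'
#' Constructs a minimal model object from reported coefficients so that
#' point predictions (and, if a covariance is supplied, confidence
#' intervals) can be reproduced from a published table without subject-
#' level data.
#'
#' @param intercept Intercept \eqn{\theta_0}, ms.
#' @param slope Concentration slope \eqn{\theta_1}, ms per ng/mL.
#' @param baseline_coef Coefficient of centred baseline QTcF (default 0;
#'   predictions are evaluated at centred baseline 0 either way).
#' @param vcov Optional 3x3 fixed-effect covariance; if omitted,
#'   predictions carry zero-width intervals.
#' @param df Degrees of freedom for t intervals (default `Inf`).
#' @param level Default confidence level.
#' @return A `cqt_fit` object supporting `predict()` and the verdict
#'   functions.
#' @examples
#' fit <- cqt_fit_from_coefficients(-2.7863, 0.0054)
#' predict(fit, conc = 86)$mean_ms
#' @export
cqt_fit_from_coefficients <- function(intercept, slope, baseline_coef = 0,
                                      vcov = NULL, df = Inf,
                                      level = 0.90) {
  beta <- c("(Intercept)" = intercept, slope = slope,
            baseline = baseline_coef)
  if (is.null(vcov)) vcov <- matrix(0, 3, 3)
  dimnames(vcov) <- list(names(beta), names(beta))
  structure(list(
    coefficients = beta, vcov = vcov, omega = NULL, sigma2 = NA_real_,
    logLik = NA_real_, baseline_centre = 0, n_subjects = NA_integer_,
    n_obs = NA_integer_, df = df, level = level, random = "manual",
    conc_scale = 1, data = NULL, fitted = NULL, residuals = NULL,
    ranef = NULL, convergence = 0L, start_used = NA_integer_,
    call = match.call()),
    class = "cqt_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
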