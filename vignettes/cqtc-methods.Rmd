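---
title: "Methods: concentration-QTc modelling in cqtr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concentration-QTc modelling in cqtr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cqtr)
```

## The analysis problem

A concentration-QTc (C-QTc) analysis asks whether a drug's effect on
cardiac repolarisation — measured as the heart-rate-corrected QT interval
— can be bounded at clinically relevant exposures. The analysis chain is:
correct QT for heart rate, remove each subject's own baseline, remove the
placebo time course, regress the resulting drug-attributable change
(ΔΔQTcF) on the time-matched plasma concentration, and read the verdict
off the confidence band of the fitted line.

`cqtr` implements this chain for two designs:

* a **4×4 crossover TQT study**: every subject receives both active doses,
  placebo and a moxifloxacin positive control in one of four balanced
  sequences, and placebo correction is *time-matched within subject*, so
  diurnal QTc variation cancels by construction;
* a **parallel-group MAD study**: cohorts randomised to active or placebo,
  corrected against the *pooled placebo mean* at the same study day and
  nominal time.

## The model

For subject $i$ and observation $j$,

$$\Delta\Delta QTcF_{ij} = (\theta_0 + b_{0i}) + (\theta_1 + b_{1i})\,C_{ij}
  + \theta_2\,(B_i - \bar B) + \varepsilon_{ij},$$

with $(b_{0i}, b_{1i}) \sim N(0, \Omega)$ unstructured,
$\varepsilon_{ij} \sim N(0, \sigma^2)$. Units are fixed: ms for intervals,
ng/mL for concentration, so $\theta_1$ is in ms per ng/mL. The model's
assumptions — no heart-rate effect (so a fixed correction is valid), no
hysteresis (a direct effect of concurrent concentration), linearity over
the observed range — are exactly the ones the diagnostic gates in
`cqt_diagnostics()` probe before modelling.

**Verdicts.** A QTc liability is excluded when the two-sided 90% CI upper
bound for mean ΔΔQTcF at the concentration of interest is strictly below
10 ms; assay sensitivity is demonstrated when the positive control's lower
bound at its observed geometric mean Cmax is strictly above 5 ms. Both
inequalities are strict, and both are *results*, not errors: the pipeline
exits successfully either way. The concentration of interest is a
steady-state geometric mean Cmax multiplied by an exposure margin
(default 2) covering intrinsic/extrinsic factors such as drug-drug
interactions.

## Estimation

$\sigma^2$ is profiled out of the restricted likelihood and the scaled
covariance $\Psi = \Omega/\sigma^2$ is parameterised by its log-Cholesky
factor, which keeps $\Omega$ positive semi-definite by construction and
leaves an unconstrained 3-parameter (or 1-parameter, for a random
intercept only) optimisation. Per-subject Woodbury algebra on cached
cross-products makes one criterion evaluation $O(q^3)$ per subject, so a
28-subject study fits in milliseconds.

Numerical choices:

* **Starts.** Three fixed deterministic starts, $\Psi \in \{0.1 I, I,
  0.01 I\}$ (i.e. $\Omega = 0.1\,\mathrm{var}(y)\,I$ at
  $\sigma^2 = \mathrm{var}(y)$, and two alternatives); Nelder-Mead
  (`reltol` 1e-12, Brent for one parameter); best criterion wins, ties to
  the first start. The fit is therefore deterministic given the data.
* **Conditioning.** Concentration is rescaled internally by its standard
  deviation (slopes of order 0.005 ms per ng/mL otherwise put five orders
  of magnitude between the variance parameters); all reported estimates,
  covariances and the criterion itself are mapped back to the stated
  ng/mL basis.
* **Degrees of freedom.** CIs use a $t$ distribution with
  `n_subjects - p` degrees of freedom, a deliberately simple and slightly
  conservative rule; point estimates do not depend on it and the rule is
  overridable through `predict(..., level)` plus the stored `df`.
* **Centring.** $\bar B$ defaults to the mean subject-level baseline over
  subjects contributing rows. Changing it shifts $\theta_0$ by
  $\theta_2\,\Delta\bar B$ and leaves $\theta_1, \theta_2$ untouched (a
  tested invariant).
* **Degenerate inputs.** All-equal concentrations or a rank-deficient
  fixed-effect design raise an estimation error naming the deficiency;
  noise-free data drive $\hat\sigma^2$ and $\hat\Omega$ to zero and are
  recovered exactly. A non-converged optimizer is reported (with its
  evaluation counts) as a warning carrying the best criterion reached.

The engine is validated three ways in the test suite: against closed-form
ANOVA estimators on a balanced random-intercept layout, against ordinary
least squares with $\Omega \equiv 0$, and against `lme4` on the full
model; a dense-matrix evaluation of the restricted likelihood confirms the
attained criterion and its local optimality under 32 fixed perturbations.

## Diagnostics

The pre-modelling checks are graphical in routine practice; here each is
quantitative with a documented threshold so a pipeline can gate on it:
heart-rate effect (|mean ΔΔHR| < 10 bpm at every timepoint, strict),
hysteresis (effect-peak lag over the concentration peak ≤ 1 h on the
nominal grid, earliest-maximum tie rule), linearity (max |LOESS − line|
over an evenly spaced grid ≤ 0.5 × the linear fit's residual SD, with a
small numerical floor so exactly linear data never flag), and a
ten-group concentration-decile summary (near-equal groups, remainder to
the lowest groups, $t$ intervals). The lag and SD-fraction thresholds are
package policy — chosen to stay quiet on linear, lag-free synthetic data
and to flag constructed violations — not literature constants; both are
arguments.

## Non-compartmental PK

AUClast uses the linear-up/log-down trapezoid (logarithmic interpolation
on declining segments between positive concentrations). The terminal
slope $\lambda_z$ is chosen by best adjusted $R^2$ among contiguous
terminal windows of ≥ 3 positive points after (and excluding) tmax, ties
to the longer window; when fewer than three such points exist the terminal
window from tmax onward (≥ 2 points) is used as a documented fallback, and
a non-positive slope leaves AUCinf/half-life undefined with a recorded
reason. The reported extrapolated-AUC fraction makes visible the
familiar bias of a finite sampling window: with 48-h sampling and a ~34-h
terminal half-life, the fitted half-life under-reads the true one, on
synthetic data exactly as in practice.

## What the simulator emulates — and what it does not

The generator inverts the analysis model: subject-level QTcF is baseline
plus a two-harmonic cosine diurnal rhythm (24 h and 12 h periods,
amplitudes 5 and 2 ms — a standard circadian representation) plus the
concentration effect with subject-level random intercept/slope, and QT is
back-computed through the Fridericia inverse from a simulated RR
(900 ± 50 ms between subjects, ± 15 ms within), so re-derivation recovers
the generated QTcF to numerical precision. Drug concentrations follow a
closed-form two-compartment oral model (ka 1.2 /h, CL/F 3.2 L/h, V1 55 L,
V2 60 L, Q 3 L/h) with log-normal inter-individual variability (CV 25% on
CL/F and V1, 20% on ka), giving biphasic decline, tmax between 0.5 and
4 h, dose-proportional exposure of roughly 220/440 ng/mL gmean Cmax at
16/32 mg, and a true terminal half-life near 34 h; the MAD design doses
once daily for 10 days by superposition (trough accumulation ratio about
2.2). The positive-control arm uses its own PK (gmean Cmax ≈ 2370 ng/mL
at 400 mg) and slope (0.0044 ms per ng/mL). Reference effect parameters:
slope 0.0054 ms per ng/mL (TQT) and −0.15 ms per ng/mL (MAD, at its
tens-of-ng/mL exposures); Ω with SDs 2 ms and 0.0015 ms per ng/mL
(correlation −0.2) and residual SD 6 ms are package choices — the
originating studies do not publish their variance components — set once
to give interval widths of the order seen in practice.

All randomness flows from one seed; per-subject substreams are derived
deterministically from it, so datasets reproduce bit-identically.

Deliberately not emulated: beat-level waveform reading and QT/RR
smoothing (intervals are consumed as already-measured numbers),
concentration assay error, effect-compartment hysteresis or Emax
saturation, carryover between crossover periods (washout ≥ 5 half-lives),
dropout beyond random row deletion, and aldosterone/cortisol
pharmacodynamics. Passing tests therefore show that the chain is correct
when its assumptions hold, not that real data satisfy them — that is what
the diagnostic gates are for on real inputs.

## Validation scale and a known, deliberate limitation

The replication studies in the test suite and acceptance script use 200
simulated studies per design (with 12-replicate smoke versions in the
module tests) — enough to put the Monte-Carlo standard error of the mean
recovered slope near 4% of its true value while keeping a full run in
minutes on one core. Both designs recover their generating slopes within
Monte-Carlo error.

One property of the real design is worth stating plainly: in a 4×4
crossover, both active dose arms are corrected against the *same* placebo
period of the same subject, and each arm's baseline is an average of a
few noisy pre-dose records. ΔΔQTcF errors are therefore positively
correlated within subject in ways the pre-specified model can only
express through its subject-level random intercept, and REML consequently
over-states the intercept's sampling variance. On the reference
configuration the replication study measures 97.5% empirical coverage for
the nominal 90% CI of mean ΔΔQTcF at 86 ng/mL (a single-arm analysis,
which removes the shared-placebo correlation, measures 92.5%). The
package keeps the pre-specified model — the same one used in practice —
and accepts the conservatism: intervals err on the wide side, which for
an exclusion analysis is the regulator-safe direction.

Other known limitations: the parallel-design placebo pooling matches on
day and nominal time across cohorts (a per-cohort switch exists); the
Day-1 baseline is shared by all days of a multiple-dose period by default
(`baseline_rule = "daily"` for day-specific baselines); and LLOQ handling
sets below-limit values to zero (flagged post-dose), appropriate for
single-dose periods where pre-dose drug is truly absent.
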