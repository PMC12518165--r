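Package: cqtr
Title: Concentration-QTc Exposure-Response Modelling for Thorough QT and
    Multiple-Ascending-Dose Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the concentration-QTc (C-QTc) analysis of thorough
    QT/QTc (TQT) crossover and multiple-ascending-dose (MAD) parallel-group
    studies: derivation of heart rate and Fridericia-corrected QT (QTcF)
    from measured ECG intervals, baseline adjustment and time-matched
    placebo correction (delta-delta QTcF), a restricted maximum likelihood
    (REML) linear mixed-effects exposure-response model with random
    intercept and concentration slope under an unstructured covariance,
    confidence-bounded predictions with ICH E14-style exclusion and assay
    sensitivity verdicts, pre-modelling assumption diagnostics (heart-rate
    effect, hysteresis, linearity, concentration deciles), non-compartmental
    pharmacokinetic analysis, and a clinical study simulator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    optparse
Config/testthat/edition: 3
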