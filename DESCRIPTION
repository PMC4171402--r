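Package: psurro
Title: Principal Stratification Tools for Evaluating Surrogate Endpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates candidate surrogate endpoints in two-arm randomized
    trials with a binary clinical outcome using the principal stratification
    framework. Provides the per-stratum risk estimands R0 and R1 and their
    risk-difference and relative-risk contrasts, classification of average
    causal necessity and sufficiency, nonparametric identification of R1
    under the constant-placebo-biomarker assumption, an exponential-tilt
    sensitivity analysis for the non-identified placebo risk curve,
    estimators exploiting augmented designs (closeout placebo vaccination,
    baseline-predictor bridge imputation, crossover), monotonicity
    diagnostics, linear-programming partial-identification bounds, and a
    counterfactual trial simulator with closed-form estimand truth for
    validating every estimator. A command-line interface orchestrates
    reproducible simulation and estimation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
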