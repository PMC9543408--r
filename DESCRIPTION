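Package: estimandr
Title: Estimand-Aligned Treatment-Effect Estimators for Longitudinal
    Depression Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the analysis toolbox needed to map common efficacy
    analyses of short-term depression trials onto ICH E9(R1) estimands:
    mixed models for repeated measures (MMRM) with unstructured
    within-subject covariance fitted by REML, ANCOVA on complete cases and
    after imputation, last-observation-carried-forward (LOCF),
    predictive-mean-matching multiple imputation, jump-to-reference (J2R)
    reference-based multiple imputation with Rubin's-rules pooling,
    pattern-mixture mixed models stratified by dropout pattern, and a
    propensity-score principal-stratum analysis.  A synthetic-trial
    generator emulates longitudinal MADRS10 outcomes, reason-specific
    treatment discontinuation and monotone plus intermittent missingness,
    and records ground-truth potential outcomes so that every estimator can
    be validated against the estimand it targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
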