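Package: svyequity
Title: Equity-Focused Subgroup Disparity Analysis for Complex Health Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies subgroup disparities in healthcare access and
    utilization from complex-survey microdata. Implements the Log Disparity
    metric with rule-based thresholds (80% rule) and a significance-gated
    six-level equity classification rendered as heatmaps, design-aware
    estimation of observed versus target subgroup shares (weighted
    proportions, Kish effective sample size, Taylor-linearized variances
    under a stratified with-replacement-PSU approximation), and
    survey-weighted logistic regression via iteratively reweighted least
    squares with linearized sandwich covariance and odds-ratio tables.
    Includes harmonization of multi-cycle survey tables (codebooks, combined
    weights, derived socioeconomic variables, cohort filters), clinical
    coding (Charlson Comorbidity Index, HbA1c strata, therapeutic drug
    categories with combination decomposition), and a synthetic-survey
    generator with known ground truth for end-to-end validation.
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
    tools,
    foreign,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich
Config/testthat/edition: 3
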