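Package: methrisk
Title: Smoking-Associated DNA Methylation Biomarkers and Mortality Risk
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying smoking-associated blood DNA methylation
    biomarkers and their value for predicting all-cause and cause-specific
    mortality in prospective cohorts.  Includes a synthetic-cohort generator
    emulating an older-adult population cohort with nine smoking-associated
    CpG sites, stratified descriptive summaries, restricted-cubic-spline
    dose-response regression, a from-scratch censored-survival engine
    (Kaplan-Meier, log-rank, Cox partial likelihood with Breslow and Efron
    ties, martingale-residual proportional-hazards diagnostics, L1-penalized
    Cox variable selection), a two-CpG lowest-quartile methylation score, and
    incremental-value evaluation of risk-prediction models (Harrell's C with
    .632-bootstrap optimism correction, categorical net reclassification
    improvement, integrated discrimination improvement, and
    Gronnesby-Borgan calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    glmnet,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
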