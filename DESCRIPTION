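Package: rmasca
Title: Repeated-Measures ASCA+ for Longitudinal Multivariate Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: ANOVA simultaneous component analysis for longitudinal
    intervention studies with multivariate outcomes (RM-ASCA+). Fits
    column-wise random-intercept linear mixed models to long-format
    repeated-measures data (unconstrained and constrained longitudinal
    data analysis, longitudinal ANCOVA, analysis of changes), decomposes
    the fitted fixed effects into interpretable effect matrices for time,
    group, and time-by-group interaction, visualizes them with principal
    component analysis, and quantifies the uncertainty of scores and
    loadings with a group-stratified nonparametric case bootstrap using
    orthogonal Procrustes rotation and percentile intervals. Includes a
    synthetic-data generator with known ground truth for parameter
    recovery studies, and a pipeline runner with a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    Matrix,
    ggplot2,
    tibble,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
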