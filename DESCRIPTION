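Package: memnorms
Title: Regression-Based Normative Data for Remotely Administered Verbal
    Memory Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for constructing regression-based normative data for
    verbal memory tests administered over videoconference: demographic
    adjustment of raw scores (transformation screening, stepwise covariate
    selection, mean-deviation refit with sign-reversed coefficients),
    Equivalent Scores from non-parametric tolerance limits, percentile
    tables, and a simulation-based comparison of two normative scoring
    systems via accuracy, ROC/AUC, Cohen's kappa and Gwet's AC1. Includes
    a Gaussian-copula synthetic cohort generator calibrated to the
    published sample structure and a noncentral-F sensitivity power
    solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
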