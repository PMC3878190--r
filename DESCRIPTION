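Package: riskroc
Title: Design and Construction of Genetic Risk Prediction Models via the
    Optimal ROC Curve
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage workflow for case-control genetic risk prediction
    built on the optimality theory of the likelihood ratio. The design
    stage estimates the optimal-ROC AUC of a proposed multilocus model
    from disease prevalence and per-SNP genotype frequencies (or
    population frequencies plus genotype relative risks), and computes
    the power and sample size needed to test the AUC against a
    threshold. The build stage grows a risk-group partition by forward
    selection over SNP genotypes (F-ROC), ranking groups by empirical
    likelihood ratio, with k-fold cross-validation, external validation,
    missing-data handling, and export of ROC curves and risk-group
    trees. A retrospective case-control genotype simulator with known
    ground truth supports end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
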