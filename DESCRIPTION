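Package: calaudit
Title: Calibration Auditing and Recalibration of Deployed Clinical Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing the calibration and fairness of a deployed
    binary clinical risk model against gold-standard outcome labels.
    Implements the hierarchical calibration framework (weak calibration via
    logistic intercept and slope, moderate calibration via Brier score and
    loess-based Eavg/ICI and Emax, strong calibration via subgroup curves),
    Harrell's concordance index and threshold-based discrimination metrics,
    recalibration-in-the-large and logistic recalibration fitted on a
    training sample and evaluated on a temporal hold-out, bootstrap
    confidence intervals and empirical two-sided p-values for subgroup
    metric differences with Bonferroni control, standardized mean
    differences for baseline-characteristics tables, and a synthetic-cohort
    generator with known subgroup-specific logit-scale miscalibration for
    end-to-end validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
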