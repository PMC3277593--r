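Package: coxen
Title: Cell-Line-Derived Chemosensitivity Predictors via Co-Expression
    Extrapolation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates multi-gene predictors of single-drug and
    combination chemotherapy response from in vitro cell-line drug activity
    and expression data.  Implements extreme-responder biomarker discovery,
    FFPE-robustness and cross-cohort direction-consistency filtering, the
    co-expression extrapolation (COXEN) "correlation of correlations"
    concordance coefficient with permutation significance, double
    cross-validated diagonal linear discriminant scoring, combination-score
    construction under drug independence, and clinical-utility evaluation
    (ROC/AUC, Youden and NPV-maximizing cutoffs, confusion metrics with Wald
    and Woolf intervals, Kaplan-Meier / log-rank survival stratification,
    covariate-adjusted logistic regression).  A seeded synthetic-data
    generator emulates cell panels, patient cohorts and paired frozen/FFPE
    profiles with planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
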