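Package: prescreg
Title: Regression-Based Detection of Prescribing Patterns from Electronic
    Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects which medications are used to treat a condition in an
    institution's outpatient population from longitudinal electronic health
    record (EHR) mention data, and which comorbidities drive preference
    among drug classes.  Implements a four-step case/control procedure:
    one-visit-per-patient cohort construction, correlation screening,
    L1-penalized logistic regression with 5-fold cross-validation and the
    one-standard-error rule, and an unpenalized logistic refit yielding
    adjusted odds ratios with Benjamini-Hochberg false discovery rate
    control.  A multinomial L1-penalized model relates comorbidities to the
    choice among drug classes, ranked by LASSO drop-out penalty.  Includes a
    synthetic EHR generator with known treatment, confounding and
    class-preference structure, a Fisher's-exact tabulation baseline, and an
    evaluation harness against a medication-indication reference.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    methods,
    glmnet,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
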