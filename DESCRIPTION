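Package: passdx
Title: PASS Diagnostic Score for Acquired Aplastic Anemia Versus Inherited
    Bone Marrow Failure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Predictive Aplastic Score System (PASS), a
    seven-factor integer point score that distinguishes acquired aplastic
    anemia (AA) from inherited bone marrow failure syndromes (IBMFS) in
    adults, together with the statistical machinery used to derive and
    validate such a score: modified Camitta severity classification,
    component-wise scoring with explicit missing-data policies, ROC AUC
    with DeLong variance and paired DeLong tests, Brier scores,
    Hosmer-Lemeshow calibration, threshold predictive-value sweeps,
    Fisher/Woolf contingency statistics, Fleiss' kappa, L1-penalized
    logistic score re-derivation with cross-validated penalty selection,
    and a synthetic cohort generator parameterized from the published
    training-cohort prevalences so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
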