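Package: absimets
Title: Metabolic Syndrome Diagnosis with A Body Shape Index and Incident
    Renal Function Decline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to diagnose metabolic syndrome under the Japanese, IDF and
    NCEP-ATPIII criteria with abdominal obesity judged either by waist
    circumference or by A Body Shape Index (ABSI >= 0.080), and to quantify
    how each of the six resulting definitions predicts new-onset renal
    function decline (eGFR < 60 mL/min/1.73 m2) over four annual screening
    visits. Includes pure calculators for BMI, ABSI, the Japanese Society of
    Nephrology eGFR equation, Friedewald LDL-C and the cardio-ankle vascular
    index (CAVI); a configurable rule engine for the six definitions with
    treatment-counting semantics; a seeded Gaussian-copula simulator of
    four-visit longitudinal cohorts with a discrete-time hazard of incident
    decline; a survival layer (Kaplan-Meier, log-rank, stratified Cox,
    age-adjusted ANCOVA means, ROC/Youden cutoffs); and an end-to-end study
    pipeline producing baseline tables, survival comparisons and Cox models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
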