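Package: cipnsense
Title: Smartphone Sensor Biomarkers for Chemotherapy-Induced Peripheral
    Neuropathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for detecting
    chemotherapy-induced peripheral neuropathy (CIPN) from smartphone
    inertial-sensor assessments and CIPN20 questionnaires. Provides a
    longitudinal patient-cohort simulator (walking, stance, finger-tapping
    and hole-peg tasks), inertial preprocessing (active-phase trimming,
    walk splitting, rotation to a gravity-aligned global frame), empirical
    mode decomposition and empirical wavelet transform feature extraction,
    ensemble minimum-redundancy-maximum-relevance feature selection with
    three-step majority voting, elastic-net classifiers with
    no-information-rate testing, paired bootstrap AUC comparison across
    monthly treatment windows, and an earliest-detection-day analysis
    based on daily Fisher exact tests with Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    e1071,
    glmnet,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
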