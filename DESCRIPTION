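Package: screenrisk
Title: Individualized Breast Cancer Risk Prediction for Screening Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to build and validate individualized breast cancer risk
    prediction models from longitudinal mammography screening data. Fits
    partly conditional Cox proportional hazards models on stacked
    woman-visit records with time-updated risk factors (family history,
    benign breast disease, mammographic features) and cluster-robust
    (Huber sandwich) standard errors; converts fits into absolute
    cumulative risk at biennial horizons up to 20 years via the Breslow
    baseline hazard; and performs split-sample internal validation with
    expected-to-observed calibration ratios (standardized-ratio confidence
    intervals) and horizon-specific AUC with Hanley-McNeil intervals. A
    synthetic screening-cohort generator with biennial visits,
    time-varying covariates and program-style censoring makes the whole
    pipeline testable without access to registry data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
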