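Package: fragscore
Title: Mortality Risk Scores and External-Validation Pipeline for Fragility Hip Fracture Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Calculators for seven published mortality risk scores for elderly
    fragility hip fracture patients (Sernbo, Jiang, Nottingham Hip Fracture
    Score, Holt, HEMA, ASAgeCoGeCC, SHiPS) together with the
    external-validation toolkit used to compare them: ROC AUC with DeLong
    confidence intervals and paired DeLong tests, Hosmer-Lemeshow
    goodness-of-fit, logistic calibration slope and intercept, confusion
    metrics at Youden-optimal or explicit thresholds, risk-stratum
    predicted-versus-observed tables, Kaplan-Meier survival machinery, a
    Hanley-McNeil sample-size calculator, and a seeded synthetic cohort
    generator emulating the covariate and outcome structure of an elderly
    fragility hip fracture population so the pipeline is exercisable
    end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    survival
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
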