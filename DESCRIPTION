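Package: stspower
Title: Smartphone Sit-to-Stand Accelerometry for Sarcopenia and Frailty Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for smartphone-based sit-to-stand (STS)
    accelerometry in older adults. Extracts peak force, rising time (T1) and
    stabilization time (T2) from triaxial acceleration traces (inverse-FFT
    low-pass filtering, triaxial norm, rule-based event detection), assesses
    trial-pair reproducibility with the two-way absolute-agreement intraclass
    correlation ICC(2,1), applies AWGS2019 sarcopenia and J-CHS frailty
    phenotype criteria, and fits internally validated elastic-net penalized
    logistic prediction models with bootstrap optimism-corrected AUC,
    logistic-recalibration calibration metrics, and Youden operating points.
    Includes a calibrated synthetic cohort and raw-trace generator with event
    ground truth for end-to-end testing at study scale.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    stats,
    graphics,
    utils,
    tools,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
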