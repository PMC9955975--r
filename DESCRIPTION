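Package: dcpkinetics
Title: Tumor-Marker Half-Life Kinetics for Predicting Ablation Outcome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-point half-life estimation for serum des-gamma-carboxy
    prothrombin (DCP, also known as PIVKA-II) around radiofrequency ablation
    of hepatocellular carcinoma, with the eligibility cascade for baseline
    and post-ablation marker levels, dichotomization of half-lives against a
    clinical cutoff, diagnostic-accuracy evaluation (confusion matrix,
    Wilson-score intervals, empirical ROC with Youden-optimal cutoff),
    serial re-elevation monitoring, recurrence-free-survival stratification
    (Kaplan-Meier, log-rank, Cox proportional hazards), and a calibrated
    synthetic-cohort generator so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
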