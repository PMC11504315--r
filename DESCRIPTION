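Package: bioscore
Title: Composite Five-Marker Prognostic Score for Prostate Cancer Biopsies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates a composite five-marker prognostic score
    ("BioScore") for predicting disease progression from prostate cancer
    biopsies. Covers the full analysis pipeline: parsing patient-level
    clinical tables (PSA, Gleason score, TNM stage, recurrence), the
    semiquantitative immunohistochemistry Intensity x Quantity score for
    eNOS, HIF-2alpha and beta4 integrin, Poisson quantification of droplet
    digital PCR counts for H19 and CDH1 transcripts with housekeeping
    normalization, per-marker ROC cut-off analysis (all-pairs and
    dichotomized AUC, Youden-optimal thresholds, bootstrap and DeLong
    confidence intervals), the 0-5 indicator-sum BioScore with high/low
    classification at the >=3 threshold, progression-free-survival
    evaluation (Kaplan-Meier, log-rank, Cox proportional hazards), and a
    synthetic-cohort generator for calibration and parameter-recovery
    experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
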