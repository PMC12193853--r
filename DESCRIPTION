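Package: hypowatch
Title: Personalized Noninvasive Hypoglycemia Detection from Smartwatch Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, leakage-safe analysis pipeline for detecting
    hypoglycemic events from consumer smartwatch physiology, with a continuous
    glucose monitor used only as the label source. Covers simulation of a
    synthetic wearable cohort (multi-rate sensor streams, diary, injected
    hypoglycemic episodes), alignment of raw streams onto a per-participant
    one-minute grid with bounded backfill/forward-fill imputation, run-length
    outcome labeling (glucose below 4 mmol/L sustained at least 15 minutes),
    day/night segmentation from diary sleep times, causal feature engineering
    (rolling cardiac and activity windows, cyclic time-of-day encoding, time
    since last meal, insulin on board), personalized gradient-boosted tree
    models evaluated with an iterative leave-hypo-segment-out split, random
    undersampling over multiple seeds, Youden-threshold event detection
    metrics, and Shapley-based feature-category importance reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    xgboost,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
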