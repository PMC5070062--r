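Package: jagaze
Title: Joint-Attention Eye-Tracking Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for toddler joint-attention
    eye-tracking studies: reading 120 Hz binocular gaze logs, calibration
    quality control, dispersion-based (I-DT) fixation detection with a 60 ms
    duration threshold, area-of-interest labelling and transition extraction,
    trial segmentation with the usual face-look and screen-look exclusion
    criteria, normalized gaze-following accuracy and normalized transition
    scores, and a group-comparison layer (ANCOVA and rank ANCOVA with a
    developmental covariate, Levene's test, partial eta squared,
    Benjamini-Hochberg FDR, distribution-gated correlations). A calibrated
    semi-Markov gaze simulator generates synthetic recordings with
    group- and task-dependent dwell and transition structure so the whole
    pipeline can be exercised and validated without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
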