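Package: tstscore
Title: Automated Immobility Scoring for the Tail Suspension Test from
    Load-Cell Force Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores mobility and immobility in the rodent tail suspension
    test (TST) from strain-gauge load-cell force recordings. Implements
    two-step session start detection (heavy zero-phase smoothing, a weighted
    period threshold, persistence-based provisional start, a
    minimum-variability baseline and local start refinement), extraction and
    1-20 Hz zero-phase band-pass filtering of the 360-s observation window,
    envelope-threshold bout segmentation with total immobility time, latency,
    cumulative and per-minute summaries, Random-Forest calibration of the
    detection threshold against manual reference scores with animal-level
    splits and grouped cross-validation, inter-method agreement metrics
    (precision, recall, F1, Cohen's kappa) on a common nearest-neighbor
    temporal grid, and synchronization of scored bouts with two-channel
    fiber-photometry calcium signals (robust isosbestic regression, dF/F,
    z-scoring, prominence-based transient detection and event-pure
    peri-onset alignment). A synthetic-data generator produces
    ground-truthed sessions, manual-annotation tracks, cohorts and coupled
    photometry traces for testing and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    randomForest,
    readxl,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
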