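Package: hypnoscore
Title: Per-Recording Supervised Sleep-Stage Scoring and Validation for Polysomnography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated wake-sleep stage scoring of polysomnography recordings
    from a brief, within-recording training set of manually scored epochs.
    Reads EDF and plain-text recordings and hypnograms on a fixed epoch grid
    (4, 10 or 30 s), extracts per-epoch spectral and amplitude features from
    EEG, EMG, EOG, ECG, accelerometer and temperature channels, fits a
    seeded ensemble classifier per recording, and applies minimum
    bout-duration consistency rules to the predicted hypnogram. Ships the
    validation apparatus used to benchmark such scorers: per-stage and
    overall F-measure agreement with rating bands, Hedges' g effect sizes,
    transition-epoch exclusion, sleep-stage reclassification schemes,
    single-channel ablation, and training-set-size response curves, together
    with a semi-Markov synthetic polysomnography generator (human, rodent
    and avian presets) providing ground-truth recordings for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
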