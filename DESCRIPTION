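Package: gazephysio
Title: Synchronized Gaze-Behavior and Physiological-Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline linking scanpath dynamics to autonomic
    physiology during prolonged scene viewing. Models gaze trajectories
    with a two-state (central/peripheral) hidden Markov model with
    Gaussian-mixture emissions and summarizes them by gaze transition
    entropy, spatial entropy of kernel-smoothed heatmaps, fixation
    duration and saccade amplitude. Extracts heart rate, RMSSD and skin
    conductance level from raw ECG/GSR channels via Pan-Tompkins beat
    detection, expresses them as baseline-relative deltas per
    three-minute window, and runs the pooled windowed correlation and
    2x2 factorial ANOVA stages. Includes a synthetic-data generator
    producing synchronized gaze and physiology sessions with known
    ground truth for recovery testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    signal,
    jsonlite,
    yaml,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr,
    car
Config/testthat/edition: 3
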