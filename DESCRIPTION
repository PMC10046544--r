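Package: qeegage
Title: qEEG-Derived Brain Biological Age and Brain Resources Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis workflow for quantitative-EEG derived
    brain biological age (BBA) and brain resources (BR). Provides a
    longitudinal two-arm cohort simulator with ground-truth brain-age
    trajectories and synthetic 19-channel resting-state EEG whose alpha-band
    content encodes the true brain age; a signal chain (EDF input/output,
    zero-phase filtering, segmentation, artifact rejection, averaged Hann
    periodograms); alpha center-of-gravity feature extraction with linear
    age calibration, BBA prediction and BR scoring; and the nonparametric
    statistics battery (Wilcoxon signed-rank, Mann-Whitney U, chi-square,
    Pearson) with exact small-sample enumeration, stratified comparisons,
    and Monte-Carlo effect-recovery utilities.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
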