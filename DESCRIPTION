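Package: emgtsci
Title: Simulation and Classification of Pre- and Post-Lesion Intramuscular EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for detecting the electrophysiological
    signature of a traumatic spinal cord lesion in intramuscular
    electromyography (EMG). Provides a motor-unit-potential-train simulator
    for labelled pre- and post-lesion recordings, a zero-phase
    Butterworth/notch signal-conditioning chain, disjoint fixed-window
    segmentation with random over-sampling and min-max normalization,
    four classical EMG amplitude features (area, RMS, turns, zero
    crossings) feeding a k-nearest-neighbours classifier, a 1-D
    convolutional neural network with global average pooling trained by
    Adam on binary cross-entropy, and a five-metric evaluation layer
    (accuracy, sensitivity, specificity, precision, F-measure) with
    stratified k-fold cross-validation and side-by-side reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
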