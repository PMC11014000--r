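Package: mwselect
Title: Mother Wavelet Selection for Wearable-Sensor Activity Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for choosing the mother wavelet that best represents
    body-worn accelerometer signals in human activity recognition (HAR)
    pipelines.  Implements an n-level wavelet packet transform with
    periodized filter-bank cascades over eleven candidate mother wavelets
    (Haar, Daubechies, Symlet, Coiflet, biorthogonal and reverse
    biorthogonal families), ranks candidates by the energy-to-Shannon-entropy
    ratio of their packet coefficients, extracts sub-band statistical
    features, and evaluates the resulting representations with stratified
    k-fold cross-validated decision-tree and support-vector-machine
    classifiers.  Includes readers for delimited tri-axial recordings,
    polyphase resampling and fixed-window segmentation, a seeded synthetic
    activity-signal generator for end-to-end testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    rpart,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
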