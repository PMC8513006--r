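Package: wristft
Title: Face-Touch Recognition from Wrist-Worn Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, preprocessing, feature extraction and evaluation
    pipeline for recognizing face-touching behavior from wrist-worn
    tri-axial accelerometer recordings. Simulates 30 Hz accelerometer
    streams for a ten-activity laboratory protocol (four face-touching,
    six non-face-touching activities), aligns recordings with annotation
    logs and trims transition noise, segments signals into non-overlapping
    windows, computes 49 time- and frequency-domain features (vector
    magnitude and per-axis statistics, gravity-angle summaries, spectral
    band power and dominant frequency), and evaluates logistic regression,
    support vector machine, decision tree and random forest classifiers
    under participant-grouped nested cross-validation for binary
    face-touch recognition and ten-class activity recognition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    rpart,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
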