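Package: harens
Title: Ensemble Activity Recognition from Waist-Worn Accelerometer Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for human activity recognition (HAR) from a single
    waist-worn triaxial accelerometer. Provides a reproducible synthetic
    data generator emulating a multi-subject laboratory protocol (stairs,
    walking, running, sitting, directed falls, lying), CSV input/output in a
    fixed ten-column schema, fixed-size overlapping sliding-window
    segmentation with impure-segment removal, and three heterogeneous
    classification pipelines: handcrafted time/frequency features with
    ReliefF ranking and a one-vs-all RBF support vector machine; per-channel
    linear discriminant projection with k-nearest-neighbour classification;
    and a per-channel one-dimensional convolutional network. Pipeline
    decisions are fused by majority vote and evaluated with
    leave-one-subject-out cross-validation using multiclass
    precision/recall/F1 reports, with deterministic parallel execution over
    folds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
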