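Package: usaug
Title: Ultrasound-Specific Data Augmentation and Annotation Auditing for
    Detection Datasets
Version: 0.1.0
Authors@R:
    person("Maintainer", "usaug", email = "usaug@example.org",
           role = c("aut", "cre"))
Description: Tools for preparing and auditing object-detection datasets of
    grayscale ultrasound images in YOLO label format. Implements
    ultrasound-specific augmentation operators (simulated defocus via a
    Gaussian convolution kernel, acoustic-shadow occlusion boxes, a
    physics-inspired graded acoustic-shadow field, and sidelobe-artifact
    overlays) alongside conventional brightness, contrast, and small-angle
    rotation transforms; class-imbalance-driven augmentation planning that
    oversamples images containing under-represented nodule categories;
    reproducible partitioning of a dataset into portions with a cumulative
    batched train/validation schedule; and annotation-quality evaluation
    against a gold standard (class-agnostic non-maximum suppression,
    confidence filtering, IoU matching, confusion matrices, per-class
    accuracy, and mean average precision). A synthetic speckle-phantom
    generator provides fully ground-truthed test datasets with a
    configurable class-imbalance profile.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jpeg,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
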