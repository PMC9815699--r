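Package: weedvision
Title: Desk-Scale Crop/Weed Object Detection with Adaptive Feature Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A testable toolkit for single-stage crop/weed object detection
    in top-down field images. Provides a synthetic field-scene generator with
    exact bounding-box ground truth, pixel-level copy-paste augmentation of
    weed objects via region-growing segmentation, three architectural network
    blocks (transformer encoder, involution-based channel feature fusion, and
    adaptively spatial feature fusion), a small width/depth-configurable
    YOLO-style detector trainable on one CPU, and a full detection evaluation
    suite (IoU matching, precision, recall, F1, AP, mAP at one or many IoU
    thresholds). All network code runs on plain arrays through a compact
    reverse-mode automatic-differentiation tape with C++ kernels.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
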