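Package: koadetect
Title: Anchor-Free Graded Lesion Detection for Knee Osteoarthritis Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compact anchor-free object-detection stack for grading knee
    osteoarthritis on radiographs by the Kellgren-Lawrence (KL) scale. Provides
    an EfficientNet-style compound-scaled backbone, a path-aggregation feature
    pyramid neck, a task-aligned detection head with spatial alignment maps,
    EIoU bounding-box regression and focal classification losses, task-aligned
    sample assignment, an AdamW training loop, VOC-style evaluation (precision,
    recall, AP, mAP, PR curves, confusion matrices, FPS), PASCAL VOC XML and
    CSV annotation I/O with stratified splitting and augmentation, and a seeded
    synthetic knee-phantom generator so the whole pipeline is trainable and
    testable on CPU without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    xml2,
    png,
    EBImage,
    yaml,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
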