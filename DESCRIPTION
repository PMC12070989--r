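Package: cervigraph
Title: Graph-Based Classification of Cervical Lesion Segmentation Masks
Version: 0.1.0
Authors@R:
    person("cervigraph", "maintainers", email = "cervigraph@example.org",
           role = c("aut", "cre"))
Description: Multi-modal graph pipeline for lesion-image classification.
    Generates class-conditioned synthetic grayscale image and labeled mask
    pairs, rasterizes polygon annotations, extracts per-region geometric,
    gray-level co-occurrence matrix (GLCM) texture and intensity features,
    builds inverse-distance weighted lesion graphs (fully connected
    originals and noise-augmented, threshold-pruned variants, serialized as
    GML), classifies graphs with a from-scratch two-layer graph
    convolutional network under stratified K-fold cross-validation with
    grid search and early stopping, and reports the full segmentation
    (Dice, IoU, precision, recall, BCE) and classification (per-class and
    macro precision/recall/F1/accuracy, confusion matrix, one-vs-rest
    ROC-AUC) metric suites, plus graph-to-mask-to-image mapping for case
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
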