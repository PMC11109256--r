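Package: dlanet
Title: Zone-Based Dual-Attention Classification of Pneumoconiosis Chest Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale reference implementation of a zone-based pipeline for
    grading pneumoconiosis severity (ILO categories 0-3) from frontal chest
    radiographs. Binary lung-field masks are split into left and right lungs
    and partitioned into upper, middle and lower zones between the lung apex
    and the diaphragm dome; per-zone convolutional classifiers refine their
    deepest feature maps with a dual attention module (squeeze-and-excitation
    channel attention followed by a 7x7-convolution spatial attention gate)
    and image-level grades are obtained by the max rule over the six zone
    predictions. Includes a synthetic radiograph generator with planted
    small-opacity profusion, histogram-matching and aspect-preserving resize
    preprocessing, stratified cross-validation training with Adam and
    reduce-on-plateau scheduling, and support-weighted one-vs-rest
    evaluation metrics (accuracy, sensitivity, specificity, F1, AUC) at zone
    and image level.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
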