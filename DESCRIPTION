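Package: woundassl
Title: Active Semi-Supervised Learning for Wound Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for growing a labelled wound-segmentation dataset from zero
    manual annotations by combining transfer learning with active
    semi-supervised learning (ASSL). Provides a CPU-trainable U-Net style
    encoder-decoder optimised with the binary focal loss, segmentation metrics
    (precision, recall, F1, IoU), a mask-validation oracle encoding three
    clinical acceptance criteria (full coverage, no holes or spurious parts,
    faithful boundaries), a round manager that iteratively promotes accepted
    model predictions to training labels, and a synthetic wound-image
    generator with exact ground truth so the whole pipeline is exercisable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
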