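Package: brainseg
Title: 3D Residual Refinement Networks for Brain Lesion Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise segmentation of brain lesions from co-registered
    multi-modality 3D MRI. Implements a compact fully-convolutional residual
    network with a multi-level 3D refinement decoder, a focal-loss objective
    for class-imbalanced dense prediction, a three-stage curriculum training
    schedule with staged data augmentation, slice-axis window planning for
    patch extraction and memory-bounded sliding-window inference, and
    Dice/sensitivity/specificity evaluation with BRATS-style label merging.
    A synthetic multi-modality phantom generator with nested lesion
    compartments supports end-to-end testing without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    EBImage,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
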