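Package: esunet3d
Title: Attention-Enhanced Full-Scale 3D U-Net Segmentation with
    Region-Specific Scaling and Dynamically Weighted Dice Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained toolkit for 3D volumetric semantic
    segmentation of co-registered PET/CT volumes.  Implements the ES-UNet
    network family (full-scale skip connections with squeeze-and-excitation
    channel attention and deep supervision), the Region Specific Scaling
    (RSS) label-aware geometric augmentation, the Dynamically Weighted Dice
    (DWD) loss with soft precision/recall coefficients, volumetric overlap
    metrics (DSC, IoU, VOE), NIfTI case handling, a seeded PET/CT-like
    phantom generator, and a CPU training/evaluation pipeline with Adam and
    cosine-annealing warm restarts.  The 3D convolution, pooling and
    resampling primitives and the reverse-mode gradient tape are built in
    (C++ via Rcpp), so no external deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
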