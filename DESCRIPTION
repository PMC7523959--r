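Package: fpfuse
Title: Nucleus-Aware Cell Instance Segmentation via Feature Pyramid Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and instance segmentation of morphologically complex
    cells (e.g. macrophages) in two-channel fluorescence microscopy images.
    Implements a two-stage region-proposal detector with a reduced ResNet-50
    backbone and feature pyramid, fusion of a frozen nucleus-trained feature
    pyramid into the cell branch by addition or concatenation, a Gaussian
    border-weighted mask loss, rule-based post-processing of predicted cell
    instances against nucleus predictions, ground-truth bootstrapping from
    raw channels (threshold segmentation plus nearest-nucleus splitting of
    multinucleate cells), a 101-point interpolated average-precision
    evaluation protocol, and a synthetic two-channel scene generator with
    pixel-perfect instance ground truth. The neural-network engine (reverse
    mode differentiation over image tensors, convolution, pooling, RoI-Align)
    is implemented in C++ via Rcpp/RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
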