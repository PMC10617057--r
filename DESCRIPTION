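Package: fpnseg
Title: Brain Tumor MRI Segmentation with a U-Net Encoder and Feature
    Pyramid Decoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Binary semantic segmentation of brain tumors in 2D MRI
    slices. Implements a fully convolutional segmentation network that
    fuses a U-Net contracting path with a feature pyramid network (FPN)
    decoder (lateral 1x1 connections, nearest-neighbour top-down merges,
    multi-scale concatenation), trained with a smoothed Dice loss, plus
    the surrounding toolchain: image/mask loading and preprocessing,
    nine paired image/mask augmentation operations, overlap-based
    evaluation metrics (Dice, Jaccard, pixel accuracy), an Adam training
    loop with early stopping, and a synthetic phantom generator so the
    whole pipeline is testable end to end on CPU without any download.
    All layers and gradients are computed by a compact reverse-mode
    autodiff engine built on Rcpp convolution kernels.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    generics,
    ggplot2,
    grDevices,
    png,
    Rcpp,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
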