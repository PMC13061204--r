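Package: hacrnet
Title: Hybrid-Attention Channel-Retention Networks for MRI Super-Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Single-image super-resolution for 2D MRI slices with a hybrid-attention
    convolutional network (HACR-Net): a shallow hybrid attention module combining
    channel and spatial gating, a stack of context-aware aggregation modules (each a
    residual block feeding a multiscale feature aggregation branch and a
    channel-retention attention branch), and sub-pixel (PixelShuffle) reconstruction.
    Includes the matching low-resolution degradation operator (Gaussian blur followed
    by bicubic decimation), L1/Adam training with full reverse-mode gradients
    implemented on an im2col+GEMM convolution engine, PSNR/SSIM image-quality metrics
    with an optional perceptual-metric plugin interface, synthetic tissue-like phantom
    generation, NIfTI/PNG I/O, and volume-level dataset splitting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    png,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
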