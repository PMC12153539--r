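Package: wsimil
Title: Weakly Supervised Attention-Based Multiple-Instance Learning for
    Whole-Slide Image Metastasis Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for classifying whole-slide
    histopathology images as benign or metastatic from slide-level labels
    alone. Provides saturation-threshold tissue segmentation, non-overlapping
    patch tiling with area-average downsampling, a pluggable patch feature
    extractor contract with a deterministic colour/texture descriptor, a
    gated attention-based multiple-instance learning (ABMIL) classifier
    trained with dropout, weight decay and early stopping, case-level
    stratified five-fold cross-validation with ensembled hold-out testing,
    bootstrap percentile confidence intervals for classification metrics, and
    attention heatmap rendering from overlapping patches. Ships a synthetic
    slide and feature-bag generator with known tumour masks and witness
    instances so the whole pipeline is exercised and tested without any real
    slides.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    withr,
    stats,
    grDevices,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
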