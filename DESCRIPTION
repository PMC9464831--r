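Package: gcldnet
Title: Gastric Cancer Lesion Detection Networks with Level Feature
    Aggregation and Attention Feature Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encoder-decoder convolutional networks for semantic
    segmentation of gastric cancer lesions in H&E-stained histopathology
    images.  Implements a level-feature-aggregation decoder (chains of
    transposed convolutions interleaved with left-to-right skip
    concatenations), a channel-attention feature-fusion head, and the
    focal Tversky loss with analytic gradients, together with Dice, BCE
    and combined losses, pixel-level evaluation metrics (Dice, Jaccard,
    accuracy, precision), a synthetic H&E-like image/mask generator for
    framework-free testing, and a CPU training pipeline (SGD with
    momentum, reduce-on-plateau Dice schedule, deep supervision).  All
    network operations run on a small reverse-mode automatic
    differentiation tape backed by im2col/col2im kernels written in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    tibble,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    dplyr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
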