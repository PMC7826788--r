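Package: lungattn
Title: Self-Attention Augmented U-Net for Lung Field Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Channel and spatial self-attention modules (X- and Y-attention)
    and an attention-augmented U-Net for segmenting lung fields in grayscale
    chest radiographs. Provides the attention blocks as composable,
    differentiable operators, a configurable encoder-decoder segmentation
    network with attention placement at any of four resolution stages,
    deterministic image pre- and post-processing (histogram equalization,
    two-largest-components filtering), Dice/sensitivity/PPV evaluation with
    cross-validated mean and standard deviation reporting, a synthetic
    lung-phantom generator for end-to-end testing without clinical data, and
    an SGD training loop with plateau learning-rate decay and early stopping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    png,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
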