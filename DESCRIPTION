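Package: fuseqa
Title: Blind Quality Assessment of Multimodal Medical Fusion Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Blind (no-reference) image quality assessment for multimodal
    medical fusion images. A small generative adversarial network hallucinates
    a best-quality reference fusion for each image under test; the per-pixel
    nuance between the image and its hallucinated reference, together with the
    image itself, feeds an attention-supervised convolutional quality network
    that regresses a radiologist-style mean opinion score (MOS, 1-5 scale).
    Includes a synthetic group-structured dataset generator emulating graded
    fusion-algorithm quality, a quality-weighted adversarial training loop,
    grouped five-fold cross-validation, and PLCC/SRCC/KRCC/RMSE evaluation
    with tidy outputs and ggplot2 visualisations. All network primitives are
    implemented in the package (Rcpp/Armadillo convolution kernels with
    explicit backpropagation), so the full pipeline trains on a single CPU
    with no external deep-learning framework and no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    png,
    yaml,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
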