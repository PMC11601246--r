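Package: phenoclip
Title: Language-Informed Cell Phenotyping for Multiplexed Tissue Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cell phenotyping for spatial proteomics that generalizes across
    heterogeneous marker panels. Single-cell image patches (one marker image,
    self-mask and neighbor-mask per channel) are encoded by a shared
    convolutional network, fused with language-derived marker embeddings by a
    channel-wise attention transformer, and classified against an arbitrary
    inference-time set of cell-type name embeddings with a focal CLIP-style
    contrastive objective. Marker positivity is read off the [CLS]-to-channel
    attention weights, and a gradient-reversal modality head encourages
    platform-invariant representations. Includes preprocessing (resampling,
    percentile normalization, patch extraction), a synthetic multiplexed-image
    simulator with ground truth, mean-intensity baselines, and evaluation
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    xgboost,
    nnet,
    pROC,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
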