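Package: mfaunet
Title: Multi-Scale Fusion Attention U-Net for Retinal Vessel Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Retinal vessel segmentation from fundus photographs with a
    multi-scale fusion attention U-Net. Implements fundus preprocessing
    (grayscale conversion, gamma correction, contrast-limited adaptive
    histogram equalization), overlapping-patch extraction and stitching, a
    compact residual encoder-decoder with a multi-scale fusion self-attention
    module on the skip paths, a parallel channel/spatial attention module in
    the decoder, and a deep-supervised multi-branch output head trained with
    binary cross-entropy and Dice losses. Includes a synthetic fundus
    generator with exact vessel ground truth, a CPU training engine built on
    an embedded reverse-mode automatic-differentiation core, and pixel-level
    evaluation metrics (accuracy, Dice, sensitivity, specificity, AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
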