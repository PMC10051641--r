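Package: wristvein
Title: Contactless Wrist-Vein Biometric Recognition Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end near-infrared wrist-vein recognition: CLAHE-based
    preprocessing, classical morphological pseudo-label generation, a modified
    U-Net segmenter trained with Dice loss, and two mask-matching engines (a
    two-pathway CNN and a weight-shared Siamese network with contrastive
    loss), together with genuine/impostor pair construction, augmentation and
    biometric evaluation (accuracy, F1, ROC/EER). Includes a synthetic
    vascular-image generator producing subject-unique vein trees with
    session-to-session jitter so every stage is trainable and testable
    without external data. The neural-network engine (convolution, pooling,
    batch normalisation, backpropagation, Adam) is implemented in the package
    via single-precision BLAS kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
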