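Package: fazseg
Title: Attention U-Net Segmentation of the Foveal Avascular Zone in OCTA Images
Version: 0.1.0
Authors@R: person("FAZ", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for segmenting the foveal avascular zone (FAZ) in en-face
    optical coherence tomography angiography (OCTA) images. Implements an
    encoder-decoder convolutional network with a per-channel feature-location
    attention block in each decoder, optimized with a weighted Dice plus
    cross-entropy joint loss, together with a plain U-Net baseline for
    ablation. Includes a self-contained float32 neural-network engine
    (im2col/GEMM convolutions, batch normalization, bilinear upsampling,
    Adam), hard-mask evaluation metrics (mean IoU, pixel accuracy, Dice), a
    synthetic OCTA-like image generator with paired ground-truth masks, PNG
    image input/output, and a command-line pipeline for training, evaluation
    and ablation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: zlib
RoxygenNote: 7.3.3
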