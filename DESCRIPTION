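Package: opuntiaseg
Title: Semantic Segmentation and Canopy Area Quantification for
    Row-Crop Orthomosaics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to quantify vegetation cover of row-planted Opuntia
    (prickly pear) fields from large RGB orthomosaics using encoder-decoder
    convolutional networks.  The package generates seeded synthetic
    cactus-field orthophotos with exact ground-truth masks, builds tiled and
    augmented training datasets (quadrant split, 160x160 rescale,
    flip/rotation augmentation), trains three self-contained segmentation
    architectures (UNet, DeepLabV3+, and a depthwise-separable UNet in the
    Xception style) with pixel-wise cross-entropy and Adam, reassembles
    full-resolution mosaic masks by tiled inference, and reports canopy
    pixel counts, areas in square metres, intersection-over-union and RMSE
    against a reference mask.  The convolutional layers and their gradients
    are implemented in C++ via 'RcppArmadillo'; no external deep-learning
    framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
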