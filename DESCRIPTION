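Package: ncaseg
Title: Multi-Scale Neural Cellular Automata with Superpixel Shape Guidance
    for Lesion Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and applies multi-scale neural cellular automata (NCA) for
    binary lesion segmentation in grayscale medical-style images, with an
    optional shape-guided refinement block built on SLIC superpixel pooling
    and unpooling. Includes a seeded synthetic phantom generator
    (textured background plus fuzzy lesion blobs with ground-truth masks),
    the standard preprocessing chain (resize, z-normalisation, outlier
    clipping, unit rescale, elastic deformation), combined soft-Dice and
    binary cross-entropy training losses, segmentation metrics (accuracy,
    Dice, mIoU, 95th-percentile Hausdorff distance), pseudo-ensemble
    inference, a label-free ensemble-agreement quality metric, and a
    command-line interface covering phantom synthesis, training, prediction,
    evaluation and quality assurance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    RNifti,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
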