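Package: tileseg
Title: Tiled Training for Multi-Label Segmentation of Panoramic
    Radiograph-Like Images
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study the effect of tile-based training on pixelwise
    multi-label semantic segmentation of wide, panoramic-radiograph-like
    images. Provides a seeded synthetic generator of dental-arch scenes with
    four overlapping restoration channels (filling, crown, root-canal
    filling, implant), exact grid tiling and stitching, a compact U-Net
    style encoder-decoder trained with soft Dice loss and Adam (plateau
    learning-rate reduction, two-stage early stopping), pixelwise
    F1/sensitivity/IoU evaluation on stitched full-image predictions, and a
    repeated k-fold cross-validation experiment runner that sweeps tile
    counts and reports mean and 95% confidence intervals per class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
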