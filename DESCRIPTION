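Package: renalus
Title: Kidney Ultrasound Segmentation and Morphometry with a Nested Strided-Convolution U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fully automated kidney biomarker measurement in 2-D
    ultrasound. Implements a nested U-Net segmentation architecture that
    downsamples with strided convolutions instead of pooling and fuses all
    top-level feature maps through deep supervision, together with the
    mask-to-biomarker measurement chains for sagittal views (kidney length by
    farthest contour pair, tailored crop, rotation to horizontal, kidney
    thickness, parenchymal thickness) and axial views (PCA orientation, hilum
    detection, axial thickness, kidney width), the ellipsoid kidney-volume
    formula, segmentation quality metrics (Dice, Jaccard, mean absolute
    distance, Hausdorff, symmetric surface distance), a biomarker agreement
    evaluator, and a synthetic kidney-phantom generator with analytically
    known ground truth for desk-scale training and verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "installed")
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
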