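Package: segassist
Title: Segmentation-Assisted Classification of Proliferative Diabetic Retinopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements segmentation-assisted staging of diabetic retinopathy
    from colour fundus photographs: a fully convolutional network (FCN) labels
    every pixel with a neovascularization (NV) probability, the resulting
    probability map is fused onto the RGB image as a fourth channel, and a
    small convolutional classifier stages the fused image into four NV-related
    categories. Ships a seeded synthetic fundus simulator (optic disc,
    branching vessels, NV webs, laser scars, IRMA-like lesions, hemorrhages
    and exudates) so the full pipeline — segmentation metrics (Dice, IOU,
    image-level presence accuracy), run-once probability-map caching,
    repeated-trial baseline versus assisted comparison with Welch's t-test,
    and one-vs-rest ROC/AUC — runs end to end on a CPU without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    tiff,
    withr,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    EBImage
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
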