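Package: uvplume
Title: Ultraviolet Plumage Colouration from Calibrated Specimen Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for quantifying ultraviolet (UV) plumage
    colouration from multi-channel (visible + UV) photographs of museum bird
    specimens, driven end-to-end by a synthetic-data generator so every stage
    is testable without an image archive. Provides polygon ground-truth
    rasterisation and classic segmentation baselines (modal thresholding with
    uppermost-component selection, seeded region growing) with IOU/precision/
    recall evaluation; grey-standard normalisation and polynomial cone-catch
    mapping into avian tetrahedral colour space; mean u, peak u and UV+
    colouration metrics; and Bayesian phylogenetic mixed models (Gibbs
    sampling animal model, gaussian and probit-binary) for phylogenetic
    heritability and ecological predictors, pooled over tree distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    mgcv,
    EBImage,
    tiff,
    png,
    yaml,
    MASS,
    dplyr,
    tibble,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    ggplot2,
    readr
Config/testthat/edition: 3
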