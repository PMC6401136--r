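Package: spermQPM
Title: Quantitative Phase Microscopy Simulation and Analysis of Sperm Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for off-axis digital holographic
    microscopy of human sperm cells. Generates parametric sperm-shaped phase
    phantoms under a volume-conserving oxidative-stress deformation,
    synthesizes off-axis interferograms under coherent (speckled) or
    pseudo-thermal illumination, reconstructs unwrapped phase maps by Fourier
    sideband filtering, converts phase to optical thickness, extracts
    morphological (maximum phase, optical volume, Monge surface area,
    sphericity) and texture (moments, histogram entropy, co-occurrence
    energy) features of the sperm head, and classifies control versus
    stressed cells with a support vector machine evaluated by ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    tools,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    e1071,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
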