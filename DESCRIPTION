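Package: nanobeam
Title: Axial Stiffness of DNA Origami Nanobeams from Spring-Network
    Models and Flow-Stretching Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Base-pair-resolution elastic spring-network models of DNA
    origami nanobeams under tension. Holliday-junction and nick elements
    carry locally degraded axial stiffness (factors alpha and beta of the
    intact duplex), which are calibrated against measured axial stiffness
    by monotone bisection and then used to predict the stiffness of other
    two-helix and multi-helix constructs. Also includes the hydrodynamic
    force model for flow-stretching experiments (plane-Poiseuille profile
    plus Stokes drag), a ground-truth-known synthetic trajectory generator
    based on the extensible worm-like chain, and the stiffness-extraction
    pipeline (symmetric-reversal quality control, unstretched length at
    10 pN, enthalpic-regime slope fit above 15 pN).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
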