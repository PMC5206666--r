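Package: holocyte
Title: Lens-Free Holographic Cytology of Cerebrospinal Fluid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for lens-free (in-line
    holographic) microscopy of cerebrospinal fluid. Provides band-limited
    angular-spectrum wave propagation, a seeded synthetic phantom generator
    with ground truth, iterative phase retrieval with twin-image
    suppression, autofocus, circle-Hough cell detection on defocused module
    images, per-cell Z-axis optical signatures (module and phase profiles),
    leukocyte/erythrocyte gating classification, conversion of counts to
    concentrations, a meningitis/non-meningitis decision rule, and
    diagnostic evaluation utilities (ROC curves, sensitivity/specificity,
    inter-operator variability statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
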