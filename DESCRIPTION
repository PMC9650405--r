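Package: vesselmorph
Title: Centerline Morphometry of the Great Vessels and Matched-Cohort Outcome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes centerline-anchored mean diameters of the aorta and main
    pulmonary artery from 3D binary segmentation masks with anisotropic voxel
    spacing, the pulmonary-artery to aorta (PA/Ao) diameter ratio and its
    enlargement classification (ratio >= 1), and a single-slice axial 2D
    emulation of manual calipers. Includes ground-truthed tubular phantom
    generators, a synthetic surgical-cohort simulator, and the downstream
    statistical stage: gated group comparisons, Spearman correlation,
    multivariable logistic regression, and 1:4 greedy propensity-score
    matching with a 0.1-SD logit caliper plus balance diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
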