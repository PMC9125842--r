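Package: wmcvol
Title: White Matter Change Volumetry and Shunt Outcome Analysis for iNPH
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Volumetry of white matter changes (WMC) on FLAIR-like brain
    images and analysis of their association with outcome after shunt
    surgery in idiopathic normal pressure hydrocephalus (iNPH).  Provides
    threshold-based semi-automatic segmentation with scripted brush
    editing, partition of WMC into periventricular (PVH) and deep (DWMH)
    compartments by ventricle-adjacency masks or the continuity-to-
    ventricle rule, voxel-count volumetry, iNPH-scale scoring with shunt
    responder classification, method-agreement statistics (intraclass
    correlation, Bland-Altman), and the covariate-adjusted regression
    battery relating lesion volumes to clinical outcome.  Includes
    generators for FLAIR-like phantoms with exact ground-truth
    compartment volumes and for simulated patient cohorts, so every step
    of the pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    RNifti,
    Rcpp,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
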