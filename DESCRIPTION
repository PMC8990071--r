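Package: apoptosens
Title: Single-Cell Apoptosis Sensitivity Modeling for Multiplexed
    Immunofluorescence Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for segmented multiplexed
    immunofluorescence single-cell tables from tissue microarray cohorts:
    image-margin and population filters, slide batch correction by
    upper-quantile normalization and rankit-based affine alignment in
    reference T-cell populations, random-forest cell phenotyping from
    lineage marker intensities, conversion of corrected intensities to
    molar concentrations against cell-line and cohort reference standards,
    deterministic ordinary differential equation models of BCL2-family
    controlled mitochondrial outer membrane permeabilization (MOMP) and of
    executioner caspase activation under XIAP/SMAC control, and
    inter-/intra-tumor heterogeneity statistics (quartile coefficient of
    dispersion, Shannon entropy, distance-capped Moran's I, and a seeded
    bootstrap of core-composition pairing). A seeded synthetic-cohort
    generator with ground truth supports testing every stage without
    patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
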