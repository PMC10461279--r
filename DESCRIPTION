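Package: atlaseval
Title: Desk-Scale Evaluation of Multi-Atlas Auto-Segmentation for Breast
    and Nodal Radiotherapy Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating atlas-based auto-segmentation of breast
    radiotherapy structures (breast CTV, axillary nodal levels, brachial
    plexus, humeral head, heart, lung) without clinical data.  Provides a
    seeded synthetic thorax-phantom cohort with controllable inter-patient
    variation (breast-board incline, chest-wall separation), a compact
    multi-atlas segmentation engine (rigid registration, optical-flow
    deformable registration, label propagation, vote fusion), segmentation
    comparison metrics (Jaccard/Dice overlap, directional extents, signed
    centroid distances and their reference-minus-test variants), atlas
    group construction with leakage checks, evaluation tables, one-way
    ANOVA and adjusted R-squared summaries, and clinically oriented
    flagging of directional contour variations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
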