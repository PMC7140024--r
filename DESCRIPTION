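Package: scaffoldperm
Title: Falling-Head Permeability, Dose-Response and Quantification
    Analytics for Decellularized Tumor Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis pipeline for decellularized colorectal
    tumor scaffold studies. Implements the falling-head permeameter forward
    model (Darcy flux, exponential column-height decay) and per-sample
    permeability estimation by relative-residual least squares, with a
    reliability protocol over repeated measurements and non-parametric group
    comparison. Adds plate-reader viability normalization to untreated
    controls, four-parameter logistic (Hill) dose-response fitting and IC50
    shift estimation between 2D and 3D culture settings, count-based marker
    and co-localization percentages, zebrafish xenograft cohort inclusion
    filters with fluorescence fold-change readouts, the study's statistical
    reporting conventions (two-group and multi-group tests with star labels),
    and seed-deterministic synthetic-data generators so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
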