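Package: cspAffinity
Title: Ligand-Binding Affinity and Expression Analysis for Insect
    Chemosensory Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis pipeline for ligand binding and
    expression profiling of insect chemosensory proteins (CSPs).
    Implements competitive fluorescence binding analysis (one-site
    saturation fits of 1-NPN titrations by nonlinear least squares or
    Scatchard linearisation, four-parameter logistic competition fits
    with an undetermined rule for weak binders, and IC50-to-Ki
    conversion), consensus analysis of ensemble docking poses across
    many homology models of one receptor (greedy energy-ordered pose
    clustering by coordinate RMSD, per-model energy aggregation,
    conversion of mean binding free energy to a dissociation constant
    at 300 K, and occupancy weighting by the free/bound model ratio),
    and relative gene-expression quantification by the 2^-ddCt method.
    Seeded synthetic-data generators emulate each assay so the whole
    pipeline is testable without instrument or docking output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
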