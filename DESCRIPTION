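Package: solseg
Title: Detection of Solenoid Repeat Regions in Protein Structures by
    Distance-Matrix Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-residue detection of alpha-, alpha/beta- and beta-solenoid
    regions in protein structures. A chain's C-alpha distance matrix is
    segmented with a small encoder-decoder convolutional network into
    per-residue solenoid class calls. The package bundles a parametric
    generator of labelled synthetic solenoid and globular C-alpha geometries,
    repeat splitting with Kabsch superposition and TM-score similarity
    matrices, benchmark metric machinery (per-class precision/recall/F1 and
    multiclass Matthews correlation), and batch structure scanning with
    majority-class chain calls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
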