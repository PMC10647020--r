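Package: confscreen
Title: Conformer Ensemble Construction and Pharmacophore Screening Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for building and evaluating small-molecule conformer
    ensembles for structure-based virtual screening. Implements
    symmetry-corrected RMSD (minimum over graph automorphisms, with optional
    Kabsch superposition), ensemble subsetting policies (unbiased sampling,
    lowest-energy ranking, and energy-sorted greedy RMSD-diversity
    filtering), interaction-derived pharmacophore feature detection, exhaustive
    query enumeration with tolerance-radius matching, F1-based screening
    metrics, docking pose success statistics with bootstrap confidence
    intervals, and a synthetic-data generator producing torsion-chain
    ensembles and planted screening libraries for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    bio3d,
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
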