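Package: phstab
Title: Trajectory Comparison and Subfamily Analysis for pH-Dependent Enzyme Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the pH-dependent stability of multidomain
    enzymes such as penicillin acylase from molecular-dynamics trajectories,
    sequence alignments and kinetic assays. Provides per-domain RMSD/RMSF
    statistics over multi-model PDB trajectories, a dynamic-time-warping
    based comparison statistic (delta-RMSD and the overlap frequency f) for
    replicate RMSD series, geometric hydrogen-bond network and
    near-attack-conformation analysis, pKa-threshold protonation assignment
    with manual overrides, subfamily-specific-position ranking in labelled
    multiple alignments, and first-order inactivation plus Michaelis-Menten
    kinetics fitting. Includes seeded synthetic-data generators for every
    input class so each statistic can be exercised against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
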