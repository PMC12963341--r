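Package: poreflux
Title: Ion Permeation and Single-Channel Current Analysis for Membrane
    Nanopores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing ion conduction through membrane
    nanopores from two directions at once: particle trajectories and
    single-channel recordings. Provides an overdamped Brownian-dynamics
    simulator of K+/Cl- motion through a cylindrical pore under a
    transmembrane field (with an optional anion-binding constriction),
    periodic-boundary-aware counting of complete directional
    translocations and their conversion to ionic current and conductance,
    constriction dwell-time analysis, Kabsch-superposition RMSD series,
    a ground-truth-labelled generator of planar-bilayer current traces,
    change-point idealization and step-like/multi-level/erratic event
    classification, and a self-contained statistical kernel including the
    Brunner-Munzel rank test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    signal,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
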