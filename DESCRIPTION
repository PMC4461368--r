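Package: torsionfel
Title: Hierarchical Conformational Substate Analysis of Backbone Torsional Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hierarchical analysis of protein free-energy landscapes
    through backbone (and side-chain) torsional degrees of freedom. Detects
    two-state torsional degrees of freedom from 1-degree circular angle
    histograms, stratifies them into decade temporal-resolution bands by mean
    transition waiting times, clusters snapshots into conformational substates
    by radix-sorted bit-encoded torsional-state keys at each resolution, builds
    cluster transition networks with hub and kinetic-trap diagnostics, labels
    transition-state-ensemble events and their lifetimes, computes structural
    properties (radius of gyration, native contacts, hydrogen bonds,
    hydrophobic solvent-accessible surface area, pairwise backbone RMSD), and
    performs dihedral principal component analysis. A seeded telegraph-process
    generator produces synthetic torsional ensembles with known kinetics so
    every stage is testable without molecular dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
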