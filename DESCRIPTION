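Package: heterosim
Title: Simulating Heterosis in Constraint-Based Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Overlays a diploid genetics layer on constraint-based metabolic
    models and breeds in-silico populations to reproduce and decompose
    heterosis (hybrid vigour) in biomass production rate. Provides flux
    balance analysis (FBA), parsimonious FBA and flux variability analysis
    on SBML (Level 3 / FBC) and COBRA-style JSON models via a built-in
    simplex solver; maps genotypes to per-reaction enzyme-capacity
    constraints sampled from FVA envelopes; simulates crosses, truncation
    selection, multi-generation inbreeding, F1/F2 production and recurrent
    selection; and quantifies mid-parent heterosis, single- versus
    multi-locus contributions, flux-heterosis correlations, reaction
    efficiency profiles and biomass-coupling classifications. Ships a
    synthetic toy-model generator so the whole pipeline is testable without
    external model downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
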