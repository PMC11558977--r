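Package: ecflux
Title: Enzyme-Constrained Flux Balance Analysis of Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction, calibration and analysis of enzyme-constrained
    metabolic models (ecGEMs). Reads and writes constraint-based models in
    COBRA-style JSON and SBML L3/FBC, splits reversible reactions and isozymes,
    attaches turnover numbers (kcat) and molecular weights to reactions, and
    bounds total enzyme mass by a proteome pool constraint. Provides FBA,
    parsimonious FBA, minimum-enzyme solutions, flux variability analysis with
    isozyme/reversibility-aware aggregation, and phenotype phase planes on top
    of a built-in simplex solver. Higher-level analyses cover overflow
    metabolism scans, carbon-source hierarchy prediction from enzyme
    efficiencies of biomass precursors, kcat calibration against measured
    growth rates and 13C fluxes, and enzyme-cost-based prediction of metabolic
    engineering targets. Includes deterministic generators for synthetic toy
    networks, proteomes and flux measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
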