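Package: forespore
Title: Two-Cell Metabolism and Gene Expression Modeling of Bacillus subtilis Sporulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and solves two-cell metabolism-and-gene-expression (ME)
    models of the sporulating Bacillus subtilis mother cell and forespore.
    A single-cell ME model with growth-rate-dependent stoichiometric
    coefficients is duplicated into mother-cell and forespore compartments
    connected by the SpoIIQ-SpoIIIA (Q-A) channel complex; the maximal
    forespore formation rate is found by bisection over linear-program
    feasibility. The package provides protein depletion and essentiality
    scans per cell, protein inactivation/blockage analysis via translation
    flux and sink-reaction maximization, flux accounting (metabolite
    production fractions, forespore:mother-cell protein partition ratios,
    channel exchange inventories, fold enrichment), a deterministic toy
    sporulation model generator for testing, JSON model serialization, and
    a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    boot
Config/testthat/edition: 3
RoxygenNote: 7.3.3
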