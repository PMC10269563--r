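Package: fermdfba
Title: Multiphase Multiobjective Dynamic Flux Balance Analysis for Batch Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamic genome-scale modelling of batch wine fermentation by
    Saccharomyces yeasts. Couples a compartmental stoichiometric model solved by
    parsimonious flux balance analysis (pFBA) to kinetic constraints on exchange
    fluxes (saturating hexose transport with ethanol inhibition, Michaelis-Menten
    ammonium uptake, first-order amino-acid uptake, hexose-proportional product
    formation) across five fermentation phases (lag, exponential growth,
    nitrogen-limited growth, stationary, decay). Includes a nitrogen-dependent
    dynamic biomass equation with an explicit growth-associated maintenance (GAM)
    decomposition, global least-squares parameter estimation against extracellular
    time series, dynamic flux-ratio analysis for comparing conditions, a curated
    toy yeast network realizing the central-carbon and higher-alcohol pathways,
    and a synthetic two-temperature fermentation data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    tools,
    xml2,
    yaml,
    jsonlite,
    lhs,
    pracma,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
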