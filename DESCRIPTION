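Package: oenoflux
Title: Multi-Phase Constraint-Based Analysis of Oenococcus oeni Batch Fermentations
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing batch fermentations of the malolactic bacterium
    Oenococcus oeni under ethanol stress with constraint-based metabolic models.
    Converts time-course optical density and extracellular concentration
    measurements into per-phase specific rates, builds an extended multi-phase
    stoichiometric system with inter-phase accumulation reactions, estimates
    non-growth-associated maintenance (NGAM) ATP by flux balance analysis,
    audits ATP/NAD(P)H/proton balances, enumerates elementary flux modes for
    substrate-product mapping, and samples the constrained flux space with an
    artificial-centering hit-and-run chain. Ships a reduced central-carbon
    network for O. oeni PSU-1 and a synthetic batch-culture generator with
    known ground truth. Includes a dense bounded-variable simplex solver so no
    external linear-programming library is required.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    xml2,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
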