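Package: corsofba
Title: Protein-Cost Minimization in the Sub-Optimal Flux Balance Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step flux balance analysis for constraint-based metabolic
    models: the biomass (or any) objective is fixed at a chosen fraction of its
    linear-programming optimum and an enzyme protein cost - molecular weight
    times a thermodynamic penalty exp(0.02 * dG0) per usable direction - is
    minimized via a cost pseudo-metabolite drained by a single sink reaction.
    Includes a Fundamental Pathways decomposition: extreme-ray enumeration of
    the flux cone after currency-metabolite removal, with exact per-pathway
    imbalance accounting in the original network, ATP-production potential via
    cheapest energy-carrier conversion, cost per ATP, and Pareto classification
    of optimal and near-optimal energy pathways. Reads SBML Level 3 (FBC) and
    BiGG-style JSON models, ships deterministic toy fixtures (glycolysis to
    lactate with balancing loops, two-pathway overflow, internal loops), and
    provides sweep, normalization, and experimental-flux comparison utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
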