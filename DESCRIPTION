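Package: combonet
Title: Comparative Signaling Network Reconstruction and Selective Low-Dose
    Drug Combination Prioritization
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs and compares perturbed kinase signaling networks of
    two cell lines from phospho-protein drug-response measurements using
    Modular Response Analysis embedded in a penalized mixed-integer quadratic
    program with indicator constraints, maps short-term signaling response to
    cell viability with linear and Michaelis-Menten-like nonlinear models,
    interpolates direct target inhibition across drug concentrations, and
    simulates and optimizes unseen low-dose three-drug combinations for
    (anti-)selectivity between the cell lines. Includes randomization-based
    significance assessment, a power analysis for validation experiments, a
    synthetic-data generator emulating the perturbation study design, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    quadprog,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
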