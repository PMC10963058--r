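Package: netkin
Title: Kinetic Reaction-Network Modelling, Simulation and Comparative Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Construction, editing and deterministic simulation of kinetic
    biochemical reaction-network models. Models are built programmatically,
    imported from SBML (Level 2/3), or derived from KEGG KGML pathway files;
    reactions carry rate laws drawn from a built-in library (mass action,
    Michaelis-Menten, competitive inhibition) or user expressions. Time
    courses and steady states are computed with stiffness-switching LSODA
    integration, single- and multi-parameter perturbation scans compare a
    perturbed against a reference state via a per-metabolite percentage-change
    statistic, and the resulting up/down-regulation pattern is mapped onto a
    bipartite metabolite/reaction network rendered to GraphML and static
    images. An offline-first access layer serves KEGG pathways and BRENDA
    enzyme parameters from local caches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    xml2,
    jsonlite,
    igraph,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
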