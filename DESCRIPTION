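Package: frugnet
Title: Plant-Frugivore Interaction Networks: Structure, Robustness and
    Keystone Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds weighted plant-frugivore consumption matrices from
    focal-tree visit records and analyses them as bipartite mutualistic
    networks. Implements species-level centrality and specialization
    indices (degree, nested rank, weighted betweenness and closeness,
    species strength, effective partners, species specificity, d and d'),
    core/periphery classification, network-level nestedness (NODF) and
    specialization (H2') with ER, CE and vaznull null-model ensembles,
    secondary-extinction robustness with single-plant ablation
    experiments, phylogenetic assemblage structure (MPD, MNTD, NRI, NTI
    against an independent-swap null) and a pulp-biomass energy-flow
    keystone score contrasted with topological indices. A synthetic-data
    module generates visit logs, matrices with tunable nestedness and
    specialization, Yule phylogenies and assemblages with controlled
    phylogenetic clustering so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    ape,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
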