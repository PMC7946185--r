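Package: glvmap
Title: Assembly Maps for Microbiome Communities Under Generalized
    Lotka-Volterra Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how microbial communities assemble. Simulates
    generalized Lotka-Volterra dynamics with a total-population cap,
    enumerates every viable subcommunity of a climax community, resolves
    all single-species and consortium invasions into a directed "assembly
    map", and analyses the map as a continuous-time Markov chain to obtain
    stationary occupancy of community states. Includes host-intervention
    extensions (consortium arrivals and a multilayer feeding network) and
    a longitudinal colonization-analysis pipeline for infant-microbiota
    style cohorts: colonization-time extraction, sparse discrete-gLV
    interaction inference, pairwise colonization-order predictability
    scores, permutation tests, and a multimembership Bayesian mixed model.
    A synthetic-data module generates archetype communities and infant
    cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
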