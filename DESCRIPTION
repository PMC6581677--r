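Package: herdnet
Title: Social Network Analysis of Managed Cattle Herds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds dyadic nearest-neighbour association networks from
    scan-sampled observations of managed herds, derives dominance
    hierarchies from agonistic interaction logs via the Modified David's
    Score, computes individual centralities (strength, eigenvector) with a
    group-size correction, tests homophily by correlating association
    matrices against attribute-difference matrices (Mantel tests with
    permutations and p-value combination), fits mixed-effects models of
    centrality on socio-demographic predictors with AICc multi-model
    inference and node-label permutation significance, and quantifies the
    impact of transfers between group compositions on dyadic relationships
    and individual centralities. Includes a synthetic-herd generator with
    latent dominance and homophily structure so the full pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    tools,
    utils,
    yaml
Suggests:
    car,
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
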