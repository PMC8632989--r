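Package: symdiv
Title: Network Diversity Analysis of Symptom Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the clinical (phenotypic) and molecular network
    diversity of symptom phenotypes. Builds a symptom co-occurrence network
    from clinical symptom-cluster records, computes a bridging-coefficient
    based node-diversity statistic on any simple graph, derives per-symptom
    molecular diversity from the maximum node diversity and degree of
    associated genes in a score-filtered protein-protein interaction
    network, and runs the comparative analyses around them: Pearson
    correlations between phenotypic and molecular diversity, rank-sum
    comparisons of symptom pairs versus single symptoms, a
    degree-preserving bipartite randomization test for shared-gene symptom
    pairs, drug-target first-order proximity counts, hypergeometric gene-set
    over-representation, and agglomerative clustering of enriched-pathway
    profiles. Includes a synthetic-data generator that emulates every input
    with heavy-tailed degree structure and tunable planted effects, and a
    config-driven end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
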