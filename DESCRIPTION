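Package: transqtl
Title: Interspecific Sample Prioritization for QTL Detection with
    Tree-Based Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects quantitative trait loci whose effects are suppressed
    by trans-regulation in interspecific hybrid populations.  Hybrid
    samples are probabilistically weighted by genotypic and phenotypic
    similarity to trait-segregating wild samples (Gower or Jaccard
    distance over top trait-correlated markers) before training random
    forest and gradient boosting marker-ranking models, so causal markers
    whose signals are masked in hybrids can still be recovered.  Includes
    a full simulation framework: wild-panel and F2 genotype simulators
    with blockwise linkage disequilibrium, additive phenotype simulation
    at a target variance explained, trans-epistatic suppression,
    correlation-graph marker filtering, a single-marker regression
    baseline, and rank-bin detection-rate evaluation over parameter
    grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    ranger,
    stats,
    utils,
    vcfR,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
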