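Package: xwgcna
Title: Cross-Species Weighted Gene Co-Expression Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds weighted gene co-expression networks for two species,
    detects species-specific and consensus modules by topological-overlap
    clustering with adaptive branch pruning, quantifies cross-species module
    preservation with permutation Z statistics (including a random "gold"
    sham module), measures eigengene-network preservation (pairwise
    preservation adjacency, scaled connectivity, and density), relates
    module eigengenes to sample traits, and derives minimal gene signatures
    with a nearest-shrunken-centroid classifier.  A synthetic-data generator
    produces paired two-species expression meta-sets with planted module
    structure so every stage can be validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
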