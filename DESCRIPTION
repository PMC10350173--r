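Package: coactnet
Title: Co-Activation Network Analysis of Brain-Wide c-Fos Activity Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds weighted co-activation networks from region-by-subject
    c-Fos cell-count tables (soft-thresholded power adjacency, topological
    overlap, hierarchical module detection), scores per-subject module
    expression by singular value decomposition, tests module preservation
    between a reference and a test network with label-permutation Z
    statistics, and screens individual regions with negative binomial
    regression under Benjamini-Hochberg correction. Also implements a fibre
    photometry pipeline (isosbestic control subtraction, dF/F, z-scoring,
    behavioural bout classification, peri-event alignment) and a synthetic
    data generator producing overdispersed counts with planted modular
    correlation structure and two-channel photometry traces with event-locked
    transients, so every stage is testable without raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    MASS,
    mclust,
    jsonlite,
    yaml
Config/testthat/edition: 3
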