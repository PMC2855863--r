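Package: devoscope
Title: Stage-Resolved Analysis of Developmental Transcriptome Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical toolkit for studying how molecular interactions vary
    across embryonic development, built around detection-call expression time
    courses. Provides probe-to-gene collapsing with majority detection calls,
    fuzzy c-means soft clustering of temporal profiles, presence-filtered
    protein-interaction subnetworks per developmental stage with centrality
    versus expression correlations, a nested linear-versus-quadratic
    ("hourglass") regression test on expressed-gene counts over log
    developmental time, randomization tests of cross-species coexpression
    conservation over developmental metastages, a pooled-resplit permutation
    test for miRNA target expression, ontology enrichment with the elim
    decorrelation algorithm, rank-based group comparisons, and a synthetic
    data generator that emulates a multi-stage two-replicate developmental
    microarray study with planted temporal groups, hub-expression coupling,
    conservation, miRNA repression, and enriched ontology terms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    utils
Suggests:
    e1071,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
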