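Package: micronet
Title: Microbial Co-Abundance Networks and Single-Sample Network Impact
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs binary microbial co-abundance networks from OTU
    abundance tables using Pearson correlation with a Monte-Carlo shuffle
    Z-score significance filter and a fixed edge budget, quantifies
    structural similarity between group networks with the Jaccard index
    against edge-shuffled null ensembles, and scores the network impact of
    individual samples through leave-one-out reconstruction, both directly
    against the sample's own cohort and indirectly against a reference
    cohort. A conventional community-analysis baseline (root Jensen-Shannon
    divergence, beta diversity, principal coordinates analysis, rank-based
    group tests) and a synthetic-community generator with planted
    correlation structure are included so the full workflow can be
    exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
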