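Package: vagmod
Title: Vaginal Microbiome Profiling, Co-Abundance Modules and Covariate
    Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis chain for large vaginal 16S amplicon cohorts:
    sample quality control by normalized read concentration, (sub)genus
    aggregation and dominance calling, compositionality-aware correlation
    networks (SparCC) with permutation significance and Markov-cluster
    module discovery, per-module eigentaxon summary scores, and a
    five-level covariate-adjusted association framework (beta diversity
    by marginal adaptive-permutation PERMANOVA, alpha diversity,
    one-versus-all community state type logistic regression, eigentaxon
    linear models, and consensus differential abundance). Ships a
    synthetic-cohort generator with planted co-abundance modules,
    dominance archetypes, run effects and covariate effects so every
    stage is verifiable without controlled-access cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    Rtsne,
    biomformat,
    mclust,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
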