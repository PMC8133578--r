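Package: regnet
Title: Query, Integrate and Evaluate Validated Transcription Factor-Target Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline compendium and analysis toolkit for experimentally
    validated transcription factor (TF) to target-gene interactions. Provides
    a boolean bracket-filter query language over edge tables with experiment
    metadata; Fisher-exact target-list and pairwise gene-set enrichment with
    Bonferroni correction and configurable backgrounds; position weight
    matrix (PWM) scanning with exact p-values by dynamic programming,
    same-motif overlap removal, per-gene-region tallies and cis-motif
    enrichment; Sungear multi-set statistics with binomial p-values and
    polygon layouts; precision/recall (AUPR) evaluation of ranked predicted
    networks against gold-standard edges, permutation significance and
    precision-cutoff pruning; Network Walking from a TF via intermediate TFs
    to its indirect targets; and a deterministic synthetic-fixture generator
    so every analysis is testable end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tibble,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
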