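Package: regulonforge
Title: Consensus Regulon Inference and Signed Transcription-Factor Target
    Calling for Single-Cell and Bulk Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct signed transcription-factor regulons from
    single-cell RNA-seq counts and companion genomic evidence. Implements
    multi-run consensus regulon inference over seeded co-expression /
    motif-pruning runs, AUCell-style rank-based regulon activity scoring
    with automatic activity thresholds, Jensen-Shannon regulon specificity
    scores, an exact negative-binomial two-group test with method-of-moments
    dispersion shrinkage, dual-contrast concordant target calling filtered
    by ChIP-peak proximity to transcription start sites, early-target
    flagging against a short-induction bulk experiment with confounder
    subtraction, and down-sampled binomial motif enrichment. A synthetic
    data generator with planted ground truth (negative-binomial counts
    under a graded regulator, knockout populations, summit-centred peaks,
    motif hit tables, and a replicated induction experiment) supports
    end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    ranger,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
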