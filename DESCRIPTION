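Package: medtail
Title: Spike-In Normalized Nascent Transcription and ChEC-Seq Occupancy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for dissecting coactivator (Mediator) tail/core
    separation experiments in budding yeast. Implements spike-in based
    median-of-ratios size factors transferred from a spike-in genome to
    experimental samples, a two-group negative-binomial Wald test for
    differential nascent transcription with Benjamini-Hochberg correction,
    cross-strain concordant gene-set derivation with coactivator-class
    composition and fold-change-magnitude summaries, and cleavage-fragment
    (ChEC-seq) coverage scoring: per-million normalized tracks, strand-aware
    upstream/TES-region enrichment ratios, Wilcoxon rank-sum group
    comparisons, and fragment-size-restricted TSS-centered average profiles.
    A synthetic-data generator with known ground truth (negative-binomial
    counts with depth factors and a fixed-composition spike-in, cleavage
    fragments with factor peaks at upstream activating regions and a short
    fragment-length mode) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
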