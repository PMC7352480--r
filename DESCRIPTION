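Package: spliceRBP
Title: Splicing Event Filtering, RBP Motif Enrichment and 3'UTR Usage
    Analysis for lncRNA Knockdown Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream analysis of alternative-splicing
    quantifications from a lncRNA knockdown experiment: read-support and
    significance filtering of splicing events (PSI/deltaPSI/posterior),
    strand-aware extraction of scan windows around cassette exons and
    alternative polyadenylation (APA) sites, position weight matrix
    scanning with exact score-distribution p-values, RNA-binding-protein
    motif enrichment against a resampled null of non-regulated events,
    isoform-fraction switching (dIF) with UTR-length consequences,
    association of distal polyA usage (PDUI) with regulator expression
    by a dual Pearson/Wilcoxon criterion, and validation of events
    against CLIP/RIP peak sets by interval overlap. Includes seeded
    synthetic-data generators with planted signal for end-to-end
    benchmarking of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
biocViews: AlternativeSplicing, MotifDiscovery, Transcriptomics,
    RNASeq, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
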