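Package: organgrn
Title: Organ-Level Gene Regulatory Network Inference, Refinement and
    Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers organ-level gene regulatory networks (GRNs) from
    expression matrices with a tree-ensemble (GENIE3-style) regression
    approach restricted to transcription-factor regulators, refines the
    ranked networks with three auxiliary evidence layers (highest
    reciprocal rank co-expression aggregated across studies, promoter
    motif occurrences, and open-chromatin motif occurrences scored with
    exact PWM p-values), and benchmarks them against ChIP-derived gold
    standards with Fisher enrichment, AUROC/AUPR and permutation nulls.
    Includes genomic annotation utilities (gene-model merging, promoter
    extraction, interval-to-gene assignment), hub ranking by an
    integrated value of influence score, target-conservation analytics,
    hypergeometric over-representation tests, and a synthetic-data
    generator that produces ground-truth regulatory systems for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    ranger,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
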