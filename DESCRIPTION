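Package: chronogrn
Title: Time-Resolved Gene Regulatory Network Construction from Expression
    and H3K27 Chromatin State Data
Version: 0.1.0
Authors@R:
    person("GRN", "Pipeline Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Infers a signed, time-resolved gene regulatory network for an
    induction time course by integrating per-gene expression direction calls
    (RNA-seq fold-change rules plus NanoString nCounter normalization and
    differential expression), paired-condition H3K27ac/H3K27me3 chromatin-state
    indexing of regulatory sites, CTCF-bounded locus assignment, and position
    weight matrix scanning of site sequences. Includes per-time-point outdegree
    and betweenness centrality for core-regulator ranking, BioTapestry and BED
    exports, and a synthetic-data module that generates a complete consistent
    input bundle (genome, annotation, peaks, expression, motifs) with a planted
    ground-truth network for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
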