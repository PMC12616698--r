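Package: resMiner
Title: Resistance-Gene-Guided Mining of Fungal Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects fungal biosynthetic gene clusters (BGCs) that encode a
    putative self-resistance gene: a close homologue of a conserved
    housekeeping "hook" protein whose homologue is duplicated elsewhere in
    the genome. Reads annotated assemblies (FASTA/GFF3 or GenBank), detects
    core biosynthetic enzymes, assembles candidate cluster regions, applies
    the resistance screen, trims cluster boundaries by cross-genome gene
    occurrence, and groups flagged clusters into gene-cluster families
    refined by shared core enzymes and hooks. Ships a deterministic
    synthetic-genome generator with planted clusters and decoys so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
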