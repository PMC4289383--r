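Package: famscape
Title: Multi-Evidence Curation and Duplication-Class Analysis of
    Multi-Domain Gene Families Across Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies members of multi-domain gene families (plant NB-LRR
    disease-resistance genes as the reference case) across sets of annotated
    genomes by combining reciprocal-best-hit orthology with length-ratio
    filtering, collinear synteny-block detection, a forward/reverse homology
    expansion screen, and a domain-architecture filter requiring both an
    NB-ARC and an LRR signal. Classifies family members as tandem-array
    duplicates (gene-spacer window), retained whole-genome-duplication
    ohnologs (Ks-filtered, depth-screened collinear blocks), or singletons,
    and compares molecular-evolution rates among the classes with a
    Nei-Gojobori (1986) Ka/Ks estimator on codon alignments. Ships a seeded
    synthetic-clade generator so the whole pipeline is testable end to end
    without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
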