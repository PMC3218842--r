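Package: hydroxyscan
Title: Genome-Wide Mapping of 5-Hydroxymethylcytosine from hmeDIP-seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for hydroxymethyl-DNA immunoprecipitation
    sequencing (hmeDIP-seq) of 5-hydroxymethylcytosine (5hmC). Takes
    deduplicated, fragment-extended aligned reads through two-control
    window/island region calling with Benjamini-Hochberg false discovery rate
    control and cross-antibody consensus, then characterises the called
    regions: normalized density tracks, expression-stratified gene
    metaprofiles, feature-centered profiles, permutation-based interval
    overlap enrichment, closest-gene and cell-specific gene-set tests,
    Watson-strand base composition and GC-skew profiles, and
    glucosyltransferase/MspI-HpaII qPCR quantification of per-locus 5hmC and
    5mC fractions. Ships a fully specified synthetic-data generator (toy
    genome with planted GC-skewed segments and 5hmC regions, matched IP,
    input and no-antibody libraries, annotations, expression and qPCR
    tables) so the whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
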