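Package: SSRmine
Title: Mining Microsatellite Markers from Expressed Sequence Tags
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An EST-to-microsatellite (SSR) marker discovery pipeline:
    redundancy reduction of expressed sequence tag sets into unique
    sequences (contigs and singletons), detection of perfect Class-I
    tandem repeats of period 2-6 with canonical motif-family grouping,
    PCR primer-pair design under length, melting-temperature, GC-content
    and product-size constraints, alignment-based classification of each
    repeat's genomic context (exon, UTR, intron, genomic) against
    annotated gene models, and compositional and empirical-test
    summaries (repeat-type frequencies by taxonomic group, amplification
    and cross-species transferability rates). Includes a seeded
    synthetic-data generator producing annotated toy genomes and
    redundant, error-bearing EST sets with repeats planted at known
    positions so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
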