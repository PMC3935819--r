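Package: rddscope
Title: Calling and Characterizing RNA-DNA Sequence Differences from Matched
    DNA and RNA Pileups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects A-to-G RNA editing and the other eleven classes of
    RNA-DNA sequence differences (RDDs) from matched DNA-seq and
    strand-specific RNA-seq pileup tables, using a stringent filter cascade
    (homozygous DNA genotype, minimum coverage on both molecules, minimum
    variant-allele level, unique mapping, cross-individual concordance).
    Quantifies the response of each site to ADAR1/ADAR2 siRNA knockdown,
    partitions enzyme targets, and derives a knockdown-based false discovery
    bound. Characterizes called sites by neighbor-base composition, 25-nt
    clustering, inverted-repeat proximity, genic-region assignment,
    hyperedited transcripts, and AU-rich-element motif enrichment, and
    relates editing to expression via RPKM fold changes, isoform switching
    and editing-expression correlation. Ships a seeded synthetic-data
    generator (Alu-dense genomes with inverted repeats, planted editing
    sites with a ground-truth ledger, binomial read noise, knockdown
    conditions) and a one-call pipeline producing a machine-readable report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
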