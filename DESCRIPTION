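Package: introtrace
Title: Trio-Based Introgression Tracing and Allele-Specific Expression
    Marker Discovery for Backcross Breeding Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for determining which genes a backcross-derived inbred
    line inherited from its donor parent, and for nominating candidate
    cis-regulatory expression markers of the introgressed trait. Reads a
    trio of variant calls (offspring plus both parents) against one
    reference, labels every variant by parental origin, assigns variants to
    gene structural parts (1 kb upstream window, UTRs, introns, coding
    exons) with synonymous/non-synonymous and in-frame/frameshift effect
    calls, aggregates to gene-level origin verdicts and a donor-inherited
    genome fraction with per-chromosome breakdown, tests inoculation
    response per genotype with a negative-binomial Wald test, classifies
    cross-genotype response patterns, and intersects donor-like expression
    patterns with donor-origin promoter variants. Includes a seeded
    backcross-pedigree simulator that emits a complete synthetic study
    (VCF, GFF3, FASTA, count matrix, design) with machine-readable ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
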