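Package: TEloci
Title: Transposable Element Insertion Discovery and Genotyping from
    Unassembled Short Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers transposable element (TE) insertion sites that are
    absent from a reference genome directly from unassembled short reads.
    Reads containing TE sequence anchored at a TE end are trimmed of the
    TE-matching portion and the remaining genomic flanks are mapped back to
    the reference; an insertion is called where left and right flanks
    overlap by exactly one copy of the element's target site duplication
    (TSD).  Reference copies of the element are classified as shared or
    reference-only, and each non-reference site is genotyped (homozygous,
    heterozygous, somatic insertion, or homozygous with a somatic excision
    event) by comparing junction-flanking read counts against reads that
    span the empty site, including detection of excision footprints from
    indel pileups.  A diploid read simulator with a truth manifest supports
    end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: C++17
Config/testthat/edition: 3
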