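Package: isoscope
Title: Isoform Discovery from Long-Read Amplicon Sequencing by Grouped
    Self-Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cataloguing transcript isoforms from error-prone
    long-read (nanopore) amplicon sequencing of a single locus. Reads are
    grouped by loosely defined exon structure from spliced genome
    alignments, error-corrected by within-group consensus in two rounds,
    and matched base-pair-exactly against a catalog of representative exon
    boundaries and admitted boundary variants. Includes a minimal built-in
    spliced aligner for desk-scale work, importers for SAM/PAF/BED12
    alignments, exon classification (stable/variable/rare, reading-frame
    symmetry, annotation status), isoform counting with confidence tiers,
    junction frequencies, replicate correlation, and a read simulator that
    emits full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tibble,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
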