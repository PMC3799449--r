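Package: mapblack
Title: Mappability Blacklists for Variant Call Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates exhaustive error-free, error-injected and SNP-injected
    sequencing reads from a reference transcriptome (or unspliced exon
    targets), audits their alignments against the encoded true origin to
    classify unmapped, multimapped and uniquely mismapped reads, derives a
    blacklist of single-nucleotide differences (SNDs) caused purely by
    mismapping, and filters candidate variant calls against that blacklist.
    Includes a binomial enrichment test for blacklist overlap and a
    deterministic toy-fixture generator (paralogous genes, multi-exon
    transcripts, truth-perturbed SAM) so the full pipeline is testable
    without external aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    IRanges,
    S4Vectors,
    GenomicRanges,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
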