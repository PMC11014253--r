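Package: methsuite
Title: Bisulfite-Aware Read Alignment and Joint Genetic-Epigenetic Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A toolkit for whole-genome bisulfite and enzymatic-conversion
    sequencing that treats the genetic and epigenetic signal in the same
    reads as one inference problem. It builds dual 3-base (C-less and
    G-less) FM-indexes over the forward+reverse reference concatenation,
    maps reads by seed-and-extend with a conversion-asymmetric substitution
    score (read T may align to reference C, and read A to reference G, but
    never the reverse), and calls SNPs and cytosine methylation jointly
    from one pileup using a six-letter allele-support alphabet {A,C,G,T,R,Y}
    with a Bayesian genotyping model. Per-read methylation and variant
    states are exported in a BED-compliant run-length-encoded format for
    allele-specific methylation analysis, with conversion-rate QC split by
    CpA/CpC/CpT context and a paired-end read simulator with full truth
    tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
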