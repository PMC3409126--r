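Package: orgvar
Title: Comparative Variant Analysis of Organellar Genome Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairwise comparison of complete chloroplast and mitochondrial
    genomes. Builds base-level alignments by maximal-exact-match anchoring,
    collinear chaining and gap closing; extracts and classifies SNPs
    (transitions/transversions), InDels, co-segregating multi-nucleotide
    substitution runs and reverse complementary variations (RCVs); censuses
    perfect microsatellites and maximal repeat pairs (forward, reverse,
    complemented, palindromic); detects the chloroplast quadripartite
    (LSC/SSC/IR) structure and plastid-derived segments in mitochondrial
    genomes; and includes a seeded simulator of organellar genome pairs with
    planted, manifest-recorded divergence for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
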