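Package: hdramp
Title: Amplicon Deep-Sequencing Analysis of CRISPR/Cas9 HDR Outcomes in Mosaic Founders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies homology-directed repair (HDR) outcomes from paired-end
    amplicon deep sequencing of CRISPR/Cas9-injected founder (F0) animals.
    Models target loci and asymmetric single-stranded oligonucleotide (ssODN)
    donors, processes raw read pairs (primer demultiplexing, length filtering,
    overlap assembly, window trimming, quality masking), collapses reads into
    N-tolerant variants, classifies variants as perfect HDR, erroneous HDR,
    wild type or other with 5'/3' junction scoring, and compares groups of
    individuals with nonparametric statistics. Includes a truth-known
    synthetic read generator emulating mosaic founder embryos so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
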