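Package: radprint
Title: De Novo RAD-Seq Genotyping and Chromosome-Print Linkage Mapping
    for Lepidopteran Backcrosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A de novo restriction-site associated DNA (RAD) sequencing
    genotyping pipeline for backcross pedigrees in taxa with achiasmatic
    female meiosis (Lepidoptera). Demultiplexes inline-barcoded paired-end
    reads, collapses 40-base RAD tags into unique sequences, clusters them
    into candidate loci with a quality-weighted distance, error-corrects
    and calls candidate RAD alleles, counts PCR-duplicate-corrected
    paired-end fragments, normalizes fragment counts across individuals by
    histogram-derived scale factors, derives maternal segregation patterns
    and pairs them into complementary "chromosome prints" (one per
    chromosome, exploiting the absence of crossing over in female
    Lepidoptera), identifies the W/Z sex chromosomes, assigns paternal
    alleles to chromosomes by allelic homology and pattern propagation,
    collapses them into multi-allele RAD markers, and builds two-point LOD
    linkage maps with map-density statistics. Includes a backcross
    read-level simulator with complete truth tables so every stage can be
    tested without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    methods,
    Rcpp,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
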