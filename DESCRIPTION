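Package: nativesel
Title: Optimum Contribution Selection with Segment-Based Kinship and
    Native-Allele Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for managing local livestock breeds with historical
    introgression. Detects shared haplotype segments (runs of homozygosity
    across individuals) in phased SNP panels, classifies marker alleles as
    native or migrant against reference-breed panels, and estimates
    segment-based kinship, kinship at native alleles and per-individual
    migrant contributions. A constrained optimum contribution selection
    (OCS) solver maximizes genetic gain under upper bounds on kinship,
    kinship at native alleles and migrant contribution, and a
    forward-in-time breeding simulator with Mendelian inheritance and
    Poisson recombination evaluates selection strategies over generations,
    including truncation selection and three OCS variants.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
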