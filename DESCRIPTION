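Package: lcpopgen
Title: Population Structure and Structural Variant Analysis from Genotype Likelihoods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for low-coverage whole-genome resequencing population
    genomics working directly from genotype likelihoods: Beagle-format input
    and output, site and sample quality filters, iterative individual-allele-
    frequency PCA with a chi-square(1) PCA-based selection scan, admixture
    estimation by expectation-maximization, Hudson's FST and allele frequency
    difference with least-cost in-water isolation-by-distance testing,
    windowed Watterson/pi/Tajima's D diversity estimators, local-PCA plus MDS
    detection of putative chromosomal inversions with karyotyping,
    heterozygosity and linkage-disequilibrium characterization, and gene
    overlap with GO-term enrichment. Includes a seeded synthetic-data
    generator (stepping-stone drift, divergently selected regions, inversion
    polymorphisms, Poisson read depth) with a machine-readable truth ledger
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    data.table,
    igraph,
    vegan,
    cluster,
    yaml,
    IRanges,
    S4Vectors,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
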