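Package: repadapt
Title: Detecting and Classifying Repeated Adaptation Across Replicate Population Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying repeated evolution across replicate ecotype pairs
    (e.g. cave vs. surface populations) from multi-population SNP data: site
    filtering and windowed summary statistics (pi, Dxy, Hudson Fst), variant and
    admixture-tract dating, the ABBA-BABA D statistic, eigen-decomposition scans of
    allele-frequency-change vectors that separate allele reuse from locus reuse,
    composite-likelihood discrimination of modes of convergent adaptation (standing
    variation, migration, independent mutation, and mixed models) against a
    coancestry null, selective-sweep intersection logic, and downstream enrichment,
    gene-length and convergent motif-loss tests. Includes a synthetic-data module
    that simulates multi-population panels with shared-drift covariance structure
    and implants sweeps of known mode for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
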