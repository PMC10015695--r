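Package: kinlow
Title: Kinship Inference from Low-Coverage Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and comparison framework for pairwise biological
    kinship estimation from low and ultra-low coverage genome data, as used
    in ancient-DNA studies. Provides a pedigree-aware forward simulator
    (panel-restricted biallelic sites, Poisson read depth, sequencing error,
    deamination-style allele flips, binomial read thinning), two genotype
    representations (random-read pseudohaploid calls and per-read binomial
    error genotype likelihoods), five kinship estimators (windowed mismatch
    with cohort normalisation, genome-wide mismatch with max-rate
    normalisation, allele-frequency halved relatedness coefficients,
    maximum-likelihood IBD coefficients k0/k1/k2 via EM, and KING/R0/R1
    allele-sharing statistics), and benchmarking utilities (coverage sweeps,
    accuracy/consistency/false-positive/false-negative metrics, Mantel
    tests) to study how the pseudohaploid and genotype-likelihood method
    families respond as coverage drops.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
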