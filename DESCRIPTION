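Package: snpkin
Title: Genomic Inbreeding and Relatedness from Genome-Wide SNP Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Marker-based estimation of inbreeding and genetic relatedness
    for small, unpedigreed populations, as used in conservation genetics of
    isolated fish stocks. Reads multi-sample VCF genotypes, applies standard
    locus filters (QUAL, minor allele frequency, an exact Hardy-Weinberg
    test, missingness), builds within-SNP-standardized additive and
    dominance genomic relationship matrices, derives individual inbreeding
    coefficients and pairwise coancestry and dominance coefficients,
    computes identity-by-state sharing and method-of-moments
    identity-by-descent probabilities (Z0/Z1/Z2, PI_HAT), embeds
    individuals by classical multidimensional scaling of IBS distances, and
    tests population differences and isolation by distance. A gene-dropping
    pedigree simulator with an exact pedigree-expectation oracle provides
    synthetic data so every estimator can be validated against classical
    quantitative-genetic expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR,
    vegan
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
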