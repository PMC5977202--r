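Package: racecline
Title: Geographic and Host-Race Genomic Differentiation from Low-Coverage SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare geographic (clinal) and host-associated genomic
    differentiation in paired host-race populations genotyped at low coverage
    (GBS/ddRAD). Implements EM estimation of allele frequencies from genotype
    likelihoods, Burrows composite linkage disequilibrium and threshold-graph
    LD classes, whole-genotype Monte Carlo resampling tests for allele
    frequency differences, cross-experiment simple and stepwise-AIC
    regressions, DAPC with a-score selection of principal components, Nei
    genetic distances with bootstrapped neighbor-joining networks, Mantel
    tests for isolation by distance and by ecology, and interchromosomal
    composite LD within and between pooled populations. Includes a synthetic
    GBS cline simulator (clinal and host-associated allele frequencies,
    inversion-like high-LD blocks, paired selection-experiment samples) used
    to validate every stage against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    ape,
    MASS,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
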