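Package: popland
Title: Population and Landscape Genetics of Pond-Breeding Amphibian Metapopulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Microsatellite population genetics and landscape-genetic inference for
    networks of amphibian breeding sites: GenePop input/output and screening filters,
    full-sibling pruning of larval samples, diversity statistics (Ho, unbiased He,
    rarefied allelic richness, Weir-Cockerham FIS), global and pairwise differentiation
    (Weir-Cockerham theta, Hedrick's G'ST, Dps, linearized FST, two-level AMOVA),
    linkage-disequilibrium effective population size with hierarchical total Ne,
    heterozygosity-excess and mode-shift bottleneck tests, Rannala-Mountain Bayesian
    individual assignment, circuit-theory landscape resistance surfaces, and
    Mantel/partial-Mantel causal modeling with maximum-likelihood population-effects
    (MLPE) mixed models. Includes a synthetic metapopulation and landscape generator
    for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
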