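Package: hybridmap
Title: Admixture Mapping in Hybrid Zones from Genotype Likelihoods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An admixture-mapping workflow for natural hybrid zones: a
    synthetic hybrid-zone generator (Balding-Nichols parental divergence,
    recombinant pedigrees, RAD-seq-like genotype likelihoods, and sparse,
    polygenic or null quantitative and binary phenotypes); genome-wide
    ancestry estimation by EM directly from genotype likelihoods and
    Hudson's F_ST; a diploid local-ancestry hidden Markov model yielding
    expected ancestry dosages; admixture linkage-disequilibrium decay;
    a Bayesian sparse linear mixed model fitted by Metropolis-within-Gibbs
    MCMC returning PVE, PGE, heritability and per-marker posterior
    inclusion probabilities; and windowed PIP peaks with a three-class
    genomic-architecture call and candidate-gene window annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    vcfR,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
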