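Package: smcmark
Title: Demographic Inference from Multiple Heritable Genomic Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference for genomes carrying several heritable
    marker types: nucleotide variants plus hyper-mutable markers such as CG
    methylation with site- and region-level epimutation. Provides a sequential
    coalescent (SMC') simulator with finite-site multi-marker mutation overlay,
    a pairwise sequentially-Markovian-coalescent hidden Markov model that
    jointly uses all markers to estimate past population sizes, recombination
    rate and unknown (epi)mutation rates by Baum-Welch or direct likelihood
    optimisation, a differentially-methylated-region segmentation HMM, and
    evaluation statistics (demography RMSE, TMRCA posterior decoding,
    genealogy-span distributions, linkage-disequilibrium decay).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
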