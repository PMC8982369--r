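Package: gpbench
Title: Benchmarking Linear and Tree-Ensemble Genomic Prediction in
    Simulated Outbred Populations
Version: 0.1.0
Authors@R:
    person("gpbench", "Maintainers", email = "gpbench@example.org",
           role = c("aut", "cre"))
Description: Simulates multigenerational outbred populations descended from
    eight founder strains (recombinant haplotype mosaics, unequal
    non-overlapping generations, fixed effects of diet, generation, litter
    and sex, and complex traits with additive and additive-by-additive
    architectures) and benchmarks four genomic-prediction models on them:
    Bayesian GBLUP, BayesB, the elastic net, and gradient-boosted regression
    trees with percentage-scale feature importance. Includes marker quality
    control (MAF, call rate, adjacent-LD pruning), phenotype precorrection,
    VanRaden genomic relationship matrices and their Hadamard squares,
    Gibbs-sampling variance components, forward validation across
    generations, generation-gap scenarios with quota-constrained reference
    sampling, GBM-importance marker preselection, and model-similarity
    analyses (top-animal and top-SNP overlap with an LD relaxation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
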