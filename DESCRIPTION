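Package: bayesrmap
Title: Simulation-Based Evaluation of BayesR Genomic Prediction and QTL Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to benchmark the BayesR four-component Bayesian mixture
    model for genomic prediction and quantitative trait locus (QTL) mapping
    on simulated data. Provides an LD-structured synthetic genotype generator
    emulating a medium-density (50k) SNP array, a phenotype simulator over
    grids of genetic architectures and heritabilities, Gibbs samplers for
    BayesR and BayesCpi implemented in C++, per-SNP and sliding-window
    posterior mapping criteria (MAP rules, posterior variances, weighted
    cumulative inclusion probabilities, Lewontin D prime), and an evaluation
    layer computing validation correlations, QTL-window detection counts and
    top-ranked AUROC values with Monte Carlo standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
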