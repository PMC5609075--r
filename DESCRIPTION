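Package: seqbayesr
Title: Bayes R Hybrid Genomic Prediction with Variant Dropping and
    Split-and-Merge Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-breed genomic prediction from sequence-scale genotype
    data with a four-component Bayes R mixture model, fitted by an
    expectation-maximization warm start followed by Gibbs sampling.
    Supports scheduled dropping of variants with low posterior inclusion
    probability (with Dirichlet prior compensation), per-chromosome
    split-and-merge analysis strategies, a pedigree-based polygenic term,
    and a multi-breed genotype/phenotype simulator with QTL architectures,
    breed effects and MAF-dependent imputation-error injection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
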