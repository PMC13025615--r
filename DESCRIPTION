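Package: kinscore
Title: Mixed-Model Association Score Tests and Neural Emulators for Related Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-trait genetic association testing in cohorts of related
    individuals. Implements pedigree kinship matrices, gene-dropping genotype
    simulation, linear mixed-model null fits, the prospective likelihood score
    (LS) and retrospective quasi-likelihood score (QLS / MASTOR) tests,
    pedigree-aware allele-frequency estimators (naive subset counting and the
    best linear unbiased estimator) with their analytic covariance structure,
    and feed-forward neural-network emulators of the tests (genotype-residual,
    raw-data, allele-frequency-feature, and max-statistic ensemble variants)
    trained with a variance-preserving loss. Includes a simulation harness for
    empirical type-I error, power, and emulation-accuracy studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
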