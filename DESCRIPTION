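Package: phyloprev
Title: Bayesian Phylogenetic Regression of Tumour Prevalence on Life-History Traits
Version: 0.1.0
Authors@R: person("Maintainer", "phyloprev", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Binomial Bayesian phylogenetic regression of species-level tumour
    prevalence (neoplasia, malignancy, lethal cancer) on log10 body mass and
    log10 maximum longevity, with species random effects correlated under an
    Ornstein-Uhlenbeck or Pagel's-lambda phylogenetic covariance structure.
    Includes an adaptive Metropolis-within-Gibbs sampler with non-centred
    species effects, convergence diagnostics (split R-hat, bulk and tail
    effective sample size), model comparison by WAIC and PSIS-LOO, posterior
    predictive checks with randomized-quantile residuals, odds-ratio and
    marginal-effect reporting, Jeffreys credible intervals for raw prevalences,
    a necropsy-shuffling resampling sensitivity study, and a synthetic-data
    generator emulating comparative-oncology necropsy datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
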