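#' Configuration for the synthetic comparative-oncology generator
#'
#' Defaults emulate the structure of the public zoo-necropsy datasets the
#' analysis targets: 100 species, necropsy counts with a hard floor of 20 and
#' a right-skewed distribution (floor + negative binomial, median ~ 38,
#' occasional counts in the hundreds), low baseline prevalence
#' (`beta0 = -3`, about 0.047), log10 body mass spanning roughly -2 to 3
#' (grams to tonnes), log10 longevity in months correlated with mass at
#' rho ~ 0.5, and a logit-scale species effect correlated along the tree.
#'
#' @param n_species number of species (>= 5; default 100).
#' @param beta0 logit-scale intercept (default -3).
#' @param beta_mass,beta_longevity,beta_interaction slopes on the log10
#'   covariates (defaults 0).
#' @param sigma_phylo SD of the phylogenetic species effect (default 0.5).
#' @param structure_family `"OU"` or `"LAMBDA"` for the species-effect
#'   correlation.
#' @param structure_param OU alpha (default 2) or Pagel's lambda.
#' @param covariate_model `"BM"` (covariates with phylogenetic signal,
#'   default) or `"iid"`.
#' @param mass_mean,mass_sd location/scale of log10 body mass (kg).
#' @param longevity_mean,longevity_sd location/scale of log10 longevity
#'   (months).
#' @param mass_longevity_cor correlation between the covariates (default 0.5).
#' @param n_min necropsy floor (default 20).
#' @param nb_mean,nb_dispersion negative-binomial excess-necropsy parameters
#'   (defaults 25 and 1.2).
#' @param seed integer RNG seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_species = 100L, beta0 = -3,
                              beta_mass = 0, beta_longevity = 0,
                              beta_interaction = 0, sigma_phylo = 0.5,
                              structure_family = c("OU", "LAMBDA"),
                              structure_param = 2,
                              covariate_model = c("BM", "iid"),
                              mass_mean = 0.5, mass_sd = 1.25,
                              longevity_mean = 2.2, longevity_sd = 0.35,
                              mass_longevity_cor = 0.5,
                              n_min = 20L, nb_mean = 25, nb_dispersion = 1.2,
                              seed = 1L) {
  structure_family <- match.arg(structure_family)
  covariate_model <- match.arg(covariate_model)
  stopifnot(n_species >= 5L, n_min >= 1L, sigma_phylo >= 0,
            abs(mass_longevity_cor) <= 1)
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Depth-normalized to 1, tips labelled sp001...spN.
#'
#' @param n_species number of tips (>= 2).
#' @param seed integer RNG seed.
#' @return a `phylo_tree`.
#' @export
simulate_yule_tree <- function(n_species, seed = 1L) {
  stopifnot(n_species >= 2L)
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  validate_tree(tree, normalize_depth = TRUE)
}

#' Draw a phylogenetically correlated vector
#'
#' One draw from MVN(0, sigma^2 R) via the Cholesky factor of the
#' correlation matrix R.
#'
#' @param tree a `phylo_tree` (used only to check labels).
#' @param structure a `correlation_structure` whose labels match the tips.
#' @param sigma marginal SD (>= 0).
#' @param seed integer RNG seed.
#' @return named numeric vector in structure-label order.
#' @export
simulate_mvn_on_tree <- function(tree, structure, sigma, seed = 1L) {
  stopifnot(inherits(structure, "correlation_structure"), sigma >= 0)
  if (!setequal(structure$labels, tree$tip.label))
    stop("structure labels do not match tree tips")
  set.seed(seed)
  z <- rnorm(length(structure$labels))
  if (sigma == 0) return(setNames(rep(0, length(z)), structure$labels))
  L <- t(chol(nearest_pd_jitter(structure$matrix)))
  setNames(sigma * drop(L %*% z), structure$labels)
}

#' Simulate a full synthetic dataset
#'
#' Generates a Yule tree, covariates (Brownian on the tree or iid),
#' phylogenetically correlated species effects u ~ MVN(0, sigma^2 R), and
#' counts k_i ~ Binomial(n_i, inv_logit(beta0 + beta x_i + u_i)). The truth
#' record stores every generating parameter for recovery tests.
#'
#' @param config a `simulation_config`.
#' @return list with `tree` (`phylo_tree`), `dataset`
#'   (`prevalence_dataset`, count column `neoplasia`), and `truth`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- simulate_yule_tree(config$n_species, seed = config$seed)
  set.seed(config$seed + 1L)
  S <- config$n_species
  if (config$covariate_model == "BM") {
    C <- bm_correlation(tree)
    L <- t(chol(nearest_pd_jitter(C$matrix)))
    g <- drop(L %*% rnorm(S)) # standardized BM deviation (unit marginal var)
    h <- drop(L %*% rnorm(S))
  } else {
    g <- rnorm(S); h <- rnorm(S)
  }
  rho <- config$mass_longevity_cor
  log10_mass <- config$mass_mean + config$mass_sd * g
  log10_longevity <- config$longevity_mean +
    config$longevity_sd * (rho * g + sqrt(1 - rho^2) * h)
  struct <- if (config$structure_family == "OU")
    ou_correlation(tree, config$structure_param)
  else lambda_correlation(tree, config$structure_param)
  u <- simulate_mvn_on_tree(tree, struct, config$sigma_phylo,
                            seed = config$seed + 2L)
  set.seed(config$seed + 3L)
  n_i <- config$n_min + rnbinom(S, size = config$nb_dispersion, mu = config$nb_mean)
  eta <- config$beta0 + config$beta_mass * log10_mass +
    config$beta_longevity * log10_longevity +
    config$beta_interaction * log10_mass * log10_longevity +
    u[tree$tip.label]
  p <- plogis(eta)
  k_i <- rbinom(S, n_i, p)
  dataset <- prevalence_dataset(tree$tip.label, n_i, list(neoplasia = k_i),
                                log10_mass = log10_mass,
                                log10_longevity = log10_longevity)
  truth <- list(beta0 = config$beta0, beta_mass = config$beta_mass,
                beta_longevity = config$beta_longevity,
                beta_interaction = config$beta_interaction,
                sigma_phylo = config$sigma_phylo,
                structure_family = config$structure_family,
                structure_param = config$structure_param,
                u = u, p = setNames(p, tree$tip.label), seed = config$seed)
  list(tree = tree, dataset = dataset, truth = truth)
}

#' Parameter-recovery experiment
#'
#' Simulates `n_seeds` datasets from `config` (seeds `config$seed + i`), fits
#' the model to each, and tabulates bias, RMSE and 95% credible-interval
#' coverage of the focal slope (and the phylogenetic SD).
#'
#' @param config a `simulation_config`.
#' @param n_seeds number of replicate simulations.
#' @param mcmc an `mcmc_config` for the fits.
#' @param predictors model predictors (default mass only).
#' @param priors a `prior_config`.
#' @return a `recovery_table` data.frame (one row per seed) with a `summary`
#'   attribute (bias, rmse, coverage per tracked parameter).
#' @export
parameter_recovery_experiment <- function(config, n_seeds = 20L,
                                          mcmc = mcmc_config(2500L, 1000L, 3L, 2L),
                                          predictors = "log10_mass",
                                          priors = prior_config()) {
  focal <- predictors[1]
  truth_slope <- switch(focal, log10_mass = config$beta_mass,
                        log10_longevity = config$beta_longevity)
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- as.integer(config$seed + 1000L * i)
    sim <- simulate_dataset(cfg)
    spec <- model_spec("neoplasia", predictors = predictors,
                       structure_family = config$structure_family)
    m <- mcmc_config(mcmc$iterations, mcmc$burn_in, mcmc$thin, mcmc$chains,
                     seed = cfg$seed)
    rows[[i]] <- tryCatch({
      fit <- sample_posterior(sim$dataset, sim$tree, spec, m, priors)
      b <- pooled_draws(fit, focal)
      s <- pooled_draws(fit, "sigma_phylo")
      data.frame(seed = cfg$seed,
                 beta_mean = mean(b), beta_median = median(b),
                 beta_lo = quantile(b, 0.025), beta_hi = quantile(b, 0.975),
                 covered = quantile(b, 0.025) <= truth_slope &
                   truth_slope <= quantile(b, 0.975),
                 sigma_median = median(s), error = FALSE)
    }, error = function(e) data.frame(seed = cfg$seed, beta_mean = NA,
                                      beta_median = NA, beta_lo = NA,
                                      beta_hi = NA, covered = NA,
                                      sigma_median = NA, error = TRUE))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- !tab$error
  attr(tab, "summary") <- list(
    truth = truth_slope,
    bias = mean(tab$beta_mean[ok]) - truth_slope,
    rmse = sqrt(mean((tab$beta_mean[ok] - truth_slope)^2)),
    coverage = mean(tab$covered[ok]),
    n_failed = sum(!ok))
  class(tab) <- c("recovery_table", class(tab))
  tab
}
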