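# shared fixtures: tiny trees, quick simulation + fit wrappers, fake fits

nwk_cherry <- "(A:1,B:1);"
nwk_3tip <- "((A:1,B:1):1,C:2);"
nwk_3tip_half <- "((A:0.5,B:0.5):0.5,C:1);"

tiny_mcmc <- function(iterations = 600L, burn_in = 200L, thin = 2L,
                      chains = 2L, seed = 1L) {
  mcmc_config(iterations, burn_in, thin, chains, seed)
}

quick_sim <- function(n_species = 20L, seed = 1L, ...) {
  simulate_dataset(simulation_config(n_species = n_species, seed = seed, ...))
}

quick_fit <- function(sim, predictors = "log10_mass", seed = 1L,
                      mcmc = tiny_mcmc(seed = seed), ...) {
  spec <- model_spec("neoplasia", predictors = predictors)
  sample_posterior(sim$dataset, sim$tree, spec, mcmc, ...)
}

# hand-assembled posterior_fit for reporting/evaluation unit tests:
# beta_draws is a (total draws) x p matrix with named columns; total even.
fake_fit <- function(beta_draws, dataset, spec, u = NULL, ll = NULL) {
  nd <- nrow(beta_draws)
  stopifnot(nd %% 2 == 0)
  S <- length(dataset$species)
  p <- ncol(beta_draws)
  par_names <- c(colnames(beta_draws), "sigma_phylo",
                 if (spec$structure_family == "OU") "alpha" else "lambda")
  draws <- array(NA_real_, c(nd / 2, 2, p + 2),
                 dimnames = list(NULL, NULL, par_names))
  for (j in seq_len(p)) draws[, , j] <- matrix(beta_draws[, j], nd / 2, 2)
  draws[, , p + 1] <- 0
  draws[, , p + 2] <- 0
  if (is.null(u)) u <- matrix(0, nd, S, dimnames = list(NULL, dataset$species))
  if (is.null(ll)) ll <- matrix(0, nd, S)
  structure(list(draws = draws, u = u, pointwise_loglik = ll,
                 lp = numeric(nd), parameters = par_names, spec = spec,
                 species = dataset$species, dataset = dataset,
                 data_hash = phyloprev:::dataset_hash(dataset, spec)),
            class = "posterior_fit")
}

expect_correlation_invariants <- function(cs, tol = 1e-8) {
  m <- cs$matrix
  expect_true(isSymmetric(m, tol = tol))
  expect_equal(unname(diag(m)), rep(1, nrow(m)), tolerance = tol)
  expect_true(all(m >= -tol & m <= 1 + tol))
  expect_true(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) >= -1e-8)
}
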