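make_ds <- function(S, n, k, lm = rnorm(S), ll = rnorm(S)) {
  prevalence_dataset(sprintf("sp%03d", 1:S), n, list(neoplasia = k),
                     log10_mass = lm, log10_longevity = ll)
}

test_that("prevalence_dataset validates counts and drops missing covariates", {
  expect_error(make_ds(3, c(10, 10, 10), c(0, 11, 2)), "k outside")
  expect_error(prevalence_dataset(c("a", "a"), c(5, 5), list(x = c(1, 1))),
               "duplicate")
  expect_message(
    ds <- prevalence_dataset(c("a", "b", "c"), c(5, 5, 5),
                             list(neoplasia = c(1, 2, 0)),
                             log10_mass = c(1, NA, 2)),
    "dropping 1 species")
  expect_equal(n_species(ds), 2L)
  expect_equal(ds$species, c("a", "c"))
})

test_that("log_likelihood matches binomial closed forms and a pmf oracle", {
  spec <- model_spec("neoplasia", predictors = "log10_mass")
  # one species, k = 0, p = 0.1 -> 20 * log(0.9)
  ds1 <- prevalence_dataset("a", 20L, list(neoplasia = 0L), log10_mass = 1)
  spec1 <- model_spec("neoplasia", predictors = "log10_mass")
  ds5 <- make_ds(5, rep(20L, 5), rep(0L, 5), lm = rnorm(5))
  eta <- qlogis(0.1)
  ll <- log_likelihood(c(eta, 0), rep(0, 5), ds5, spec1)
  expect_equal(ll, 5 * 20 * log(0.9), tolerance = 1e-12)

  # beta = 0, u = 0 -> p = 1/2 everywhere
  set.seed(4)
  S <- 8; n <- sample(10:40, S, replace = TRUE); k <- rbinom(S, n, 0.3)
  ds <- make_ds(S, n, k)
  expect_equal(log_likelihood(c(0, 0), rep(0, S), ds, spec),
               sum(lchoose(n, k)) - sum(n) * log(2), tolerance = 1e-12)

  # random configurations vs per-species dbinom summation
  set.seed(11)
  for (rep in 1:25) {
    S <- sample(3:12, 1)
    n <- sample(5:200, S, replace = TRUE)
    k <- rbinom(S, n, runif(1, 0.01, 0.6))
    ds <- make_ds(S, n, k)
    beta <- rnorm(2, 0, 2); u <- rnorm(S, 0, 1)
    X <- design_matrix(ds, spec)
    p <- plogis(drop(X %*% beta) + u)
    oracle <- sum(dbinom(k, n, p, log = TRUE))
    expect_equal(log_likelihood(beta, u, ds, spec), oracle, tolerance = 1e-10)
  }
  expect_error(log_likelihood(c(0, 0, 0), rep(0, S), ds, spec), "beta length")
})

test_that("log_prior sums independent densities and handles support", {
  spec_ou <- model_spec("neoplasia", predictors = "log10_mass",
                        structure_family = "OU")
  spec_la <- model_spec("neoplasia", predictors = "log10_mass",
                        structure_family = "LAMBDA")
  pr <- prior_config()
  # density oracle at beta = 0, sigma = 0, alpha = 0
  oracle <- 2 * dnorm(0, 0, 10, log = TRUE) +
    log(2) + dt(0, df = 3, log = TRUE) - log(2.5) +
    log(2) + dnorm(0, 0, 5, log = TRUE)
  expect_equal(log_prior(c(0, 0), 0, 0, spec_ou, pr), oracle, tolerance = 1e-12)

  expect_identical(log_prior(c(0, 0), 0, 1.2, spec_la, pr), -Inf)
  expect_identical(log_prior(c(0, 0), -0.1, 0.5, spec_la, pr), -Inf)
  expect_identical(log_prior(c(0, 0), 1, -0.5, spec_ou, pr), -Inf)

  # doubling the sigma prior scale changes only the sigma term
  pr2 <- prior_config(sigma_scale = 5)
  d1 <- log_prior(c(1, -1), 2, 1, spec_ou, pr) - log_prior(c(1, -1), 2, 1, spec_ou, pr2)
  d2 <- log_prior(c(0, 3), 2, 4, spec_ou, pr) - log_prior(c(0, 3), 2, 4, spec_ou, pr2)
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("model_spec and mcmc_config enforce their invariants", {
  expect_error(model_spec("neoplasia", predictors = character(0)), "predictor")
  expect_error(model_spec("neoplasia", predictors = "log10_mass",
                          include_interaction = TRUE), "both predictors")
  expect_error(mcmc_config(1000, 1000), "exceed")
  expect_error(mcmc_config(chains = 1), "chains")
  expect_error(model_spec("neoplasia", structure_mode = "fixed",
                          fixed_value = NA), "fixed_value")
})

test_that("sample_posterior is seed-deterministic and draw counts match", {
  sim <- quick_sim(15, seed = 5, beta_mass = 0.5)
  f1 <- quick_fit(sim, seed = 3)
  f2 <- quick_fit(sim, seed = 3)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$pointwise_loglik, f2$pointwise_loglik)
  f3 <- quick_fit(sim, seed = 4)
  expect_false(identical(f1$draws, f3$draws))
  m <- tiny_mcmc()
  expect_equal(dim(f1$draws)[1], (m$iterations - m$burn_in) %/% m$thin)
  expect_equal(dim(f1$draws)[2], m$chains)
  # support invariants
  expect_true(all(pooled_draws(f1, "sigma_phylo") >= 0))
  expect_true(all(pooled_draws(f1, "alpha") >= 0))
})

test_that("all-zero counts force low posterior prevalence", {
  set.seed(2)
  tr <- simulate_yule_tree(20, seed = 8)
  ds <- prevalence_dataset(tr$tip.label, rep(50L, 20),
                           list(neoplasia = rep(0L, 20)),
                           log10_mass = rnorm(20))
  spec <- model_spec("neoplasia", predictors = "log10_mass")
  fit <- sample_posterior(ds, tr, spec, tiny_mcmc(seed = 2))
  X <- design_matrix(ds, spec)
  beta <- cbind(pooled_draws(fit, "(Intercept)"), pooled_draws(fit, "log10_mass"))
  pbar <- colMeans(plogis(tcrossprod(beta, X) + fit$u))
  expect_true(all(pbar < 0.05))
})

test_that("sigma_phylo = 0 reduces to an unstructured binomial GLM", {
  sim <- quick_sim(60, seed = 13, beta_mass = 0.6, sigma_phylo = 0,
                   nb_mean = 150)
  spec <- model_spec("neoplasia", predictors = "log10_mass")
  fit <- sample_posterior(sim$dataset, sim$tree, spec,
                          tiny_mcmc(3000, 1000, 2, 2, seed = 6), fix_sigma = 0)
  glm_fit <- glm(cbind(sim$dataset$counts$neoplasia,
                       sim$dataset$n_necropsies - sim$dataset$counts$neoplasia)
                 ~ sim$dataset$covariates$log10_mass, family = binomial)
  expect_equal(mean(pooled_draws(fit, "(Intercept)")),
               unname(coef(glm_fit)[1]), tolerance = 0.05)
  expect_equal(mean(pooled_draws(fit, "log10_mass")),
               unname(coef(glm_fit)[2]), tolerance = 0.05)
  expect_true(all(pooled_draws(fit, "sigma_phylo") == 0))
})

test_that("fit_all_specs builds the model grid and tags failures", {
  sim <- quick_sim(12, seed = 21)
  ds <- sim$dataset
  ds$counts$malignant <- pmin(ds$counts$neoplasia, 1L)
  m <- tiny_mcmc(300, 100, 2, 2)
  fits1 <- fit_all_specs(ds, sim$tree, "neoplasia", m)
  expect_length(fits1, 4L)
  expect_true(all(vapply(fits1, inherits, TRUE, "posterior_fit")))
  fits2 <- fit_all_specs(ds, sim$tree, c("neoplasia", "malignant"), m)
  expect_length(fits2, 8L)
  fits3 <- fit_all_specs(ds, sim$tree, c("neoplasia", "absent"), m)
  expect_true(inherits(fits3[["absent.mass.OU"]], "fit_error"))
})
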