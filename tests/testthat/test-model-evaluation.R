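test_that("split_rhat behaves on iid, separated, and constant chains", {
  set.seed(1)
  iid <- matrix(rnorm(4000), 1000, 4)
  r <- split_rhat(iid)
  expect_gt(r, 0.99); expect_lt(r, 1.02)

  sep <- cbind(rnorm(500, 0, 1), rnorm(500, 10, 1))
  expect_gt(split_rhat(sep), 1.5)

  expect_warning(rc <- split_rhat(matrix(2, 100, 4)), "constant")
  expect_equal(rc, 1)
  expect_error(split_rhat(matrix(1:6, 3, 2)), "draws")
})

test_that("split_rhat is affine invariant", {
  set.seed(2)
  x <- matrix(rnorm(2000), 500, 4)
  expect_equal(split_rhat(x), split_rhat(3.7 * x - 11), tolerance = 1e-12)
})

test_that("ess matches iid and analytic AR(1) references", {
  set.seed(3)
  iid <- matrix(rnorm(4000), 1000, 4)
  e <- ess(iid, "bulk")
  expect_gt(e, 3200); expect_lt(e, 4800)
  expect_gt(ess(iid, "tail"), 1000)

  # AR(1) with phi = 0.9: ESS ~ N (1 - phi) / (1 + phi)
  phi <- 0.9
  ar <- sapply(1:4, function(i) {
    x <- numeric(2000); x[1] <- rnorm(1)
    for (t in 2:2000) x[t] <- phi * x[t - 1] + rnorm(1) * sqrt(1 - phi^2)
    x
  })
  analytic <- 8000 * (1 - phi) / (1 + phi)
  expect_lt(abs(ess(ar, "bulk") - analytic) / analytic, 0.25)

  expect_warning(e0 <- ess(matrix(1, 100, 2), "bulk"), "constant")
  expect_equal(e0, 0)
  # cap: never above 1.5x total draws
  set.seed(9)
  anti <- matrix(rnorm(2000), 500, 4)
  expect_lte(ess(anti, "bulk"), 1.5 * 2000)
})

test_that("waic matches trivial cases and a brute-force oracle", {
  ll1 <- matrix(c(-1, -2, -3), 1, 3)
  w1 <- waic(rbind(ll1, ll1)) # two identical draws
  expect_equal(w1$waic, -2 * sum(ll1))
  expect_equal(w1$p_waic, 0)

  set.seed(5)
  ll <- matrix(rnorm(100 * 5, -2, 0.7), 100, 5)
  w <- waic(ll)
  # direct formula evaluation, no log-sum-exp path
  lppd <- log(colMeans(exp(ll)))
  pw <- apply(ll, 2, var)
  expect_equal(w$waic, -2 * sum(lppd - pw), tolerance = 1e-8)
  expect_equal(w$p_waic, sum(pw), tolerance = 1e-10)

  # adding c to every entry shifts criteria by exactly -2 * S * c
  cshift <- 1.37
  expect_equal(waic(ll + cshift)$waic, w$waic - 2 * 5 * cshift, tolerance = 1e-8)
  expect_error(waic(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("psis_loo handles degenerate weights, shifts, and outliers", {
  ll_const <- matrix(rep(c(-1.5, -2.5, -0.5), each = 50), 50, 3)
  res <- suppressWarnings(psis_loo(ll_const))
  expect_equal(res$looic, -2 * sum(ll_const[1, ]))
  expect_true(all(res$pareto_k == -Inf))
  expect_equal(res$looic, waic(ll_const)$waic)

  set.seed(6)
  ll <- matrix(rnorm(2000 * 8, -2, 0.4), 2000, 8)
  w <- waic(ll)
  l <- psis_loo(ll)
  expect_lt(abs(l$looic - w$waic), 2 * w$se_waic + 1)
  # shift invariance
  l2 <- psis_loo(ll + 0.9)
  expect_equal(l2$looic, l$looic - 2 * 8 * 0.9, tolerance = 1e-6)

  # inject one heavy outlier draw for species 1 -> its k dominates
  ll_out <- ll
  ll_out[1, 1] <- -40
  k <- psis_loo(ll_out)$pareto_k
  expect_equal(which.max(k), 1L)
})

test_that("compare_structures prefers lower WAIC and checks hashes", {
  sim <- quick_sim(12, seed = 31)
  spec_ou <- model_spec("neoplasia", predictors = "log10_mass",
                        structure_family = "OU")
  spec_la <- model_spec("neoplasia", predictors = "log10_mass",
                        structure_family = "LAMBDA")
  ll <- matrix(rnorm(200 * 12, -2, 0.3), 200, 12)
  beta <- cbind("(Intercept)" = rnorm(200), log10_mass = rnorm(200))
  f_ou <- fake_fit(beta, sim$dataset, spec_ou, ll = ll)
  f_la <- fake_fit(beta, sim$dataset, spec_la, ll = ll)
  cmp <- compare_structures(f_ou, f_la)
  expect_equal(cmp$delta_waic, 0)
  expect_true(cmp$indistinguishable)
  expect_equal(cmp$preferred, "OU")

  f_la_better <- fake_fit(beta, sim$dataset, spec_la, ll = ll + 1)
  cmp2 <- compare_structures(f_ou, f_la_better)
  expect_equal(cmp2$preferred, "LAMBDA")
  expect_equal(cmp2$delta_waic, -2 * 12, tolerance = 1e-6)

  other <- quick_sim(12, seed = 32)
  f_other <- fake_fit(beta, other$dataset, spec_la, ll = ll)
  expect_error(compare_structures(f_ou, f_other), "same data")
  expect_error(compare_structures(f_la, f_ou), "OU fit")
})

test_that("structure comparison favours OU on strongly OU data", {
  # scaled-down simulation check: with alpha = 5 and sizeable phylo effect,
  # the OU fit should not lose clearly to lambda on average
  deltas <- numeric(5)
  for (i in 1:5) {
    sim <- quick_sim(30, seed = 40 + i, sigma_phylo = 1.2, structure_param = 5)
    m <- tiny_mcmc(800, 300, 2, 2, seed = i)
    f_ou <- sample_posterior(sim$dataset, sim$tree,
                             model_spec("neoplasia", "log10_mass",
                                        structure_family = "OU"), m)
    f_la <- sample_posterior(sim$dataset, sim$tree,
                             model_spec("neoplasia", "log10_mass",
                                        structure_family = "LAMBDA"), m)
    deltas[i] <- compare_structures(f_ou, f_la)$delta_waic
  }
  # positive delta = OU preferred; demand no systematic lambda win
  expect_gt(mean(deltas), -2)
})

test_that("posterior predictive PIT residuals are calibrated on own data", {
  pvals <- numeric(4); means <- numeric(4)
  for (i in 1:4) {
    sim <- quick_sim(40, seed = 50 + i, beta_mass = 0.4, sigma_phylo = 0.4)
    fit <- quick_fit(sim, seed = i, mcmc = tiny_mcmc(800, 300, 2, 2, seed = i))
    ppc <- posterior_predictive_check(fit, seed = i)
    expect_true(all(ppc$pit >= 0 & ppc$pit <= 1))
    pvals[i] <- ppc$uniformity_p
    means[i] <- mean(ppc$pit)
  }
  expect_gte(sum(pvals > 0.01), 3)
  expect_true(all(means > 0.3 & means < 0.7))
})

test_that("posterior predictive check flags gross misfit", {
  # fit to half-prevalence data, then check against all-zero counts
  set.seed(7)
  tr <- simulate_yule_tree(30, seed = 77)
  ds_half <- prevalence_dataset(tr$tip.label, rep(40L, 30),
                                list(neoplasia = rbinom(30, 40, 0.5)),
                                log10_mass = rnorm(30))
  spec <- model_spec("neoplasia", predictors = "log10_mass")
  fit <- sample_posterior(ds_half, tr, spec, tiny_mcmc(seed = 7))
  ds_zero <- prevalence_dataset(tr$tip.label, rep(40L, 30),
                                list(neoplasia = rep(0L, 30)),
                                log10_mass = ds_half$covariates$log10_mass)
  ppc <- posterior_predictive_check(fit, dataset = ds_zero, seed = 7)
  expect_true(all(ppc$pit < 0.2))
  expect_lt(ppc$uniformity_p, 0.01)
})

test_that("convergence_report aggregates gates", {
  sim <- quick_sim(15, seed = 61, beta_mass = 0.3)
  fit <- quick_fit(sim, seed = 61)
  rep <- convergence_report(fit)
  expect_s3_class(rep, "convergence_report")
  expect_named(rep$table, c("parameter", "rhat", "ess_bulk", "ess_tail",
                            "lag1_autocorr"))
  expect_type(rep$pass, "logical")
  # relaxed thresholds must pass for a healthy short run
  relaxed <- convergence_report(fit, rhat_tol = 0.2, ess_min = 5, ac_max = 1)
  expect_true(relaxed$pass)
})
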