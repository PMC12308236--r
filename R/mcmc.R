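#' Fit the binomial phylogenetic prevalence regression by MCMC
#'
#' Samples the posterior of the regression coefficients, the phylogenetic SD
#' `sigma_phylo`, the correlation-structure parameter (OU `alpha` or Pagel's
#' `lambda`), and the species effects `u` with an adaptive random-walk
#' Metropolis-within-Gibbs sampler. Species effects use the non-centred
#' parameterization `u = sigma_phylo * L(theta) %*% z` with `L` the Cholesky
#' factor of the phylogenetic correlation matrix, so the sampler remains
#' well-behaved when `sigma_phylo` is small. Runs are exactly reproducible
#' given `mcmc$seed`.
#'
#' @param dataset a `prevalence_dataset`; species must be a subset of the
#'   tree tips (unmatched species are dropped with a message).
#' @param tree a validated `phylo_tree`.
#' @param spec a `model_spec`.
#' @param mcmc an `mcmc_config`.
#' @param priors a `prior_config`.
#' @param fix_sigma optional fixed value for `sigma_phylo` (e.g. 0 reduces the
#'   model to an unstructured binomial GLM); `NULL` (default) samples it.
#' @return a `posterior_fit` object: `draws` is a 3-d array
#'   \[kept-iteration, chain, parameter\] of the scalar parameters; `u` and
#'   `pointwise_loglik` are (total draws) x S matrices stacked chain-major;
#'   `lp` the log-posterior trace.
#' @export
sample_posterior <- function(dataset, tree, spec, mcmc = mcmc_config(),
                             priors = prior_config(), fix_sigma = NULL) {
  stopifnot(inherits(dataset, "prevalence_dataset"), inherits(spec, "model_spec"),
            inherits(mcmc, "mcmc_config"))
  dataset <- match_to_tree(dataset, tree)
  S <- n_species(dataset)
  if (S < 5L) stop("at least 5 species required to fit the model")
  k <- dataset$counts[[spec$response]]
  if (is.null(k)) stop("dataset has no count column '", spec$response, "'")
  X <- design_matrix(dataset, spec)
  tmat_full <- shared_path_times(tree)
  idx <- match(dataset$species, rownames(tmat_full))
  tmat <- tmat_full[idx, idx, drop = FALSE]
  depth <- tree_depth(tree)
  family_code <- if (spec$structure_family == "OU") 0L else 1L
  estimate <- spec$structure_mode == "estimate"
  init_param <- if (estimate) {
    if (family_code == 0L) 1 else 0.5
  } else spec$fixed_value

  n_keep <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thin
  p <- ncol(X)
  par_names <- c(colnames(X), "sigma_phylo",
                 if (spec$structure_family == "OU") "alpha" else "lambda")
  draws <- array(NA_real_, dim = c(n_keep, mcmc$chains, p + 2L),
                 dimnames = list(NULL, NULL, par_names))
  u_all <- matrix(NA_real_, n_keep * mcmc$chains, S)
  ll_all <- matrix(NA_real_, n_keep * mcmc$chains, S)
  lp_all <- numeric(n_keep * mcmc$chains)
  accept_theta <- numeric(mcmc$chains)

  pooled <- (sum(k) + 0.5) / (sum(dataset$n_necropsies) + 1)
  for (ch in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed + 1000L * (ch - 1L))
    beta_init <- c(qlogis(pooled), rep(0, p - 1L)) + rnorm(p, 0, 0.3)
    res <- .mwg_chain(k, dataset$n_necropsies, X, tmat, depth,
                      family_code, estimate, init_param,
                      mcmc$iterations, mcmc$burn_in, mcmc$thin,
                      priors$beta_sd, priors$sigma_df, priors$sigma_scale,
                      priors$alpha_sd,
                      !is.null(fix_sigma), if (is.null(fix_sigma)) 0 else fix_sigma,
                      beta_init)
    draws[, ch, seq_len(p)] <- res$beta
    draws[, ch, p + 1L] <- res$sigma
    draws[, ch, p + 2L] <- res$param
    rows <- (ch - 1L) * n_keep + seq_len(n_keep)
    u_all[rows, ] <- res$u
    ll_all[rows, ] <- res$pointwise_loglik
    lp_all[rows] <- res$lp
    accept_theta[ch] <- res$accept_theta
  }
  colnames(u_all) <- colnames(ll_all) <- dataset$species

  structure(list(draws = draws, u = u_all, pointwise_loglik = ll_all,
                 lp = lp_all, parameters = par_names,
                 spec = spec, mcmc = mcmc, priors = priors,
                 species = dataset$species, dataset = dataset,
                 data_hash = dataset_hash(dataset, spec),
                 accept_theta = accept_theta),
            class = "posterior_fit")
}

# cheap content hash to guard model comparisons against mismatched data
dataset_hash <- function(dataset, spec = NULL) {
  v <- c(dataset$species, dataset$n_necropsies,
         if (!is.null(spec)) dataset$counts[[spec$response]] else unlist(dataset$counts))
  sum(as.numeric(utf8ToInt(paste(v, collapse = "|"))) *
        (seq_along(utf8ToInt(paste(v, collapse = "|"))) %% 97 + 1))
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("posterior_fit: response '%s', predictors %s, %s structure (%s)\n",
              x$spec$response, paste(x$spec$predictors, collapse = " + "),
              x$spec$structure_family, x$spec$structure_mode))
  cat(sprintf("  %d retained draws (%d chains x %d)\n",
              dim(x$draws)[1] * dim(x$draws)[2], dim(x$draws)[2], dim(x$draws)[1]))
  print(posterior_summary(x))
  invisible(x)
}

#' Per-chain draw matrix for one parameter
#' @param fit a `posterior_fit`.
#' @param parameter parameter name (see `fit$parameters`).
#' @return matrix \[kept-iteration, chain\].
#' @export
chain_draws <- function(fit, parameter) {
  if (!parameter %in% fit$parameters) stop("unknown parameter: ", parameter)
  fit$draws[, , parameter, drop = TRUE]
}

#' Pooled posterior draws for one parameter
#' @inheritParams chain_draws
#' @return numeric vector, chains stacked.
#' @export
pooled_draws <- function(fit, parameter) {
  as.vector(chain_draws(fit, parameter))
}

#' Posterior summary table
#' @param fit a `posterior_fit`.
#' @param probs quantile levels (default 2.5/50/97.5%).
#' @return data.frame with mean and quantiles per parameter.
#' @export
posterior_summary <- function(fit, probs = c(0.025, 0.5, 0.975)) {
  out <- t(vapply(fit$parameters, function(p) {
    d <- pooled_draws(fit, p)
    c(mean = mean(d), quantile(d, probs))
  }, numeric(1L + length(probs))))
  as.data.frame(out)
}

#' Fit the standard grid of model specifications
#'
#' For each response: mass-only, longevity-only, mass + longevity, and
#' mass + longevity + interaction, under the chosen structure family. Fit
#' errors are caught and returned as `fit_error` entries tagged with their
#' spec rather than aborting the grid.
#'
#' @param dataset a `prevalence_dataset`.
#' @param tree a `phylo_tree`.
#' @param responses character vector of tumour types to model.
#' @param mcmc an `mcmc_config`.
#' @param structure_family `"OU"` or `"LAMBDA"`.
#' @param priors a `prior_config`.
#' @return named list of `posterior_fit` (or `fit_error`) objects.
#' @export
fit_all_specs <- function(dataset, tree, responses, mcmc = mcmc_config(),
                          structure_family = "OU", priors = prior_config()) {
  pred_sets <- list(
    mass = list(p = "log10_mass", int = FALSE),
    longevity = list(p = "log10_longevity", int = FALSE),
    mass_longevity = list(p = c("log10_mass", "log10_longevity"), int = FALSE),
    interaction = list(p = c("log10_mass", "log10_longevity"), int = TRUE))
  fits <- list()
  for (resp in responses) {
    for (nm in names(pred_sets)) {
      ps <- pred_sets[[nm]]
      spec <- model_spec(resp, predictors = ps$p, include_interaction = ps$int,
                         structure_family = structure_family)
      key <- paste(resp, nm, structure_family, sep = ".")
      fits[[key]] <- tryCatch(
        sample_posterior(dataset, tree, spec, mcmc, priors),
        error = function(e) structure(list(spec = spec, error = conditionMessage(e)),
                                      class = "fit_error"))
    }
  }
  fits
}
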