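#' Construct a species-level prevalence dataset
#'
#' Bundles per-species necropsy denominators, tumour-case counts by type, and
#' the two log10 life-history covariates. Counts must satisfy
#' 0 <= k <= n for every species and type; rows with missing covariates are
#' dropped with a message (listwise complete-record use, no imputation).
#'
#' @param species character vector of species labels (unique after
#'   space/underscore normalization).
#' @param n_necropsies positive integer vector, one per species.
#' @param counts named list or data.frame of non-negative integer case counts
#'   (e.g. `neoplasia`, `malignant`, `lethal`), each aligned with `species`.
#' @param log10_mass log10 body mass (kg) per species.
#' @param log10_longevity log10 maximum longevity (months) per species.
#' @return a `prevalence_dataset` object (a list with validated fields).
#' @export
prevalence_dataset <- function(species, n_necropsies, counts,
                               log10_mass = NULL, log10_longevity = NULL) {
  species <- normalize_label(as.character(species))
  S <- length(species)
  if (S < 1L) stop("dataset must contain at least one species")
  if (anyDuplicated(species)) stop("duplicate species: ", species[duplicated(species)][1L])
  n_necropsies <- as.integer(n_necropsies)
  if (length(n_necropsies) != S || anyNA(n_necropsies) || any(n_necropsies < 1L))
    stop("n_necropsies must be positive integers, one per species")
  counts <- lapply(as.list(counts), as.integer)
  if (length(counts) == 0L) stop("at least one tumour-count column required")
  for (nm in names(counts)) {
    k <- counts[[nm]]
    if (length(k) != S) stop("count column '", nm, "' length mismatch")
    bad <- which(is.na(k) | k < 0L | k > n_necropsies)
    if (length(bad))
      stop("count column '", nm, "': k outside [0, n] at row(s) ",
           paste(head(bad, 5L), collapse = ", "))
  }
  cov <- list(log10_mass = log10_mass, log10_longevity = log10_longevity)
  cov <- cov[!vapply(cov, is.null, logical(1))]
  keep <- rep(TRUE, S)
  for (nm in names(cov)) {
    x <- as.numeric(cov[[nm]])
    if (length(x) != S) stop("covariate '", nm, "' length mismatch")
    keep <- keep & is.finite(x)
    cov[[nm]] <- x
  }
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message("dropping ", n_drop, " species with missing covariates")
    species <- species[keep]; n_necropsies <- n_necropsies[keep]
    counts <- lapply(counts, `[`, keep)
    cov <- lapply(cov, `[`, keep)
  }
  structure(list(species = species, n_necropsies = n_necropsies,
                 counts = counts, covariates = cov, n_dropped = n_drop),
            class = "prevalence_dataset")
}

#' @export
print.prevalence_dataset <- function(x, ...) {
  cat(sprintf("prevalence_dataset: %d species, counts: %s\n",
              length(x$species), paste(names(x$counts), collapse = ", ")))
  cat(sprintf("  necropsies: min %d, median %g, max %d\n",
              min(x$n_necropsies), median(x$n_necropsies), max(x$n_necropsies)))
  invisible(x)
}

#' Number of species in a dataset
#' @param dataset a `prevalence_dataset`.
#' @return integer count.
#' @export
n_species <- function(dataset) length(dataset$species)

#' Load a prevalence dataset from CSV and match it to a tree
#'
#' Expected columns: `species`, `n_necropsies`, one or more of `k_neoplasia`,
#' `k_malignant`, `k_lethal`, plus `body_mass_kg` and `max_longevity_months`
#' (log10-transformed on load). Species are matched to tree tips after
#' space/underscore normalization; unmatched species are dropped with a
#' message. Rows with k > n are rejected with their row numbers.
#'
#' @param path CSV file path.
#' @param tree optional `phylo_tree`; when given, species are intersected with
#'   its tips.
#' @return a `prevalence_dataset`.
#' @export
load_dataset <- function(path, tree = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "n_necropsies")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("dataset CSV missing column(s): ", paste(miss, collapse = ", "))
  kcols <- intersect(c("k_neoplasia", "k_malignant", "k_lethal"), names(df))
  if (!length(kcols)) stop("dataset CSV has no k_* tumour-count column")
  for (kc in kcols) {
    bad <- which(df[[kc]] > df$n_necropsies)
    if (length(bad))
      stop("rows with k > n_necropsies in '", kc, "': ",
           paste(head(bad, 10L), collapse = ", "))
  }
  counts <- setNames(lapply(kcols, function(kc) df[[kc]]), sub("^k_", "", kcols))
  lm10 <- if ("body_mass_kg" %in% names(df)) log10(df$body_mass_kg) else NULL
  ll10 <- if ("max_longevity_months" %in% names(df)) log10(df$max_longevity_months) else NULL
  ds <- prevalence_dataset(df$species, df$n_necropsies, counts,
                           log10_mass = lm10, log10_longevity = ll10)
  if (!is.null(tree)) ds <- match_to_tree(ds, tree)
  ds
}

#' Restrict a dataset to species present in a tree
#' @param dataset a `prevalence_dataset`.
#' @param tree a `phylo_tree`.
#' @return the filtered dataset.
#' @export
match_to_tree <- function(dataset, tree) {
  tips <- normalize_label(tree$tip.label)
  keep <- dataset$species %in% tips
  if (!any(keep)) stop("no species in common between dataset and tree")
  if (any(!keep))
    message("dropping ", sum(!keep), " species absent from tree: ",
            paste(head(dataset$species[!keep], 5L), collapse = ", "))
  subset_dataset(dataset, keep)
}

subset_dataset <- function(dataset, keep) {
  structure(list(species = dataset$species[keep],
                 n_necropsies = dataset$n_necropsies[keep],
                 counts = lapply(dataset$counts, `[`, keep),
                 covariates = lapply(dataset$covariates, `[`, keep),
                 n_dropped = dataset$n_dropped),
            class = "prevalence_dataset")
}

#' Write a prevalence dataset to the standard CSV schema
#' @param dataset a `prevalence_dataset`.
#' @param path output path.
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- data.frame(species = dataset$species, n_necropsies = dataset$n_necropsies)
  for (nm in names(dataset$counts)) df[[paste0("k_", nm)]] <- dataset$counts[[nm]]
  if (!is.null(dataset$covariates$log10_mass))
    df$body_mass_kg <- 10^dataset$covariates$log10_mass
  if (!is.null(dataset$covariates$log10_longevity))
    df$max_longevity_months <- 10^dataset$covariates$log10_longevity
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Specify a single regression model
#'
#' @param response tumour type; must name a count column of the dataset.
#' @param predictors character subset of `c("log10_mass", "log10_longevity")`,
#'   non-empty, order kept.
#' @param include_interaction add the mass x longevity product term (requires
#'   both predictors).
#' @param structure_family `"OU"` or `"LAMBDA"` phylogenetic correlation.
#' @param structure_mode `"estimate"` (parameter sampled jointly) or
#'   `"fixed"`.
#' @param fixed_value structure parameter value when `structure_mode="fixed"`.
#' @return a `model_spec` object.
#' @export
model_spec <- function(response, predictors = c("log10_mass", "log10_longevity"),
                       include_interaction = FALSE,
                       structure_family = c("OU", "LAMBDA"),
                       structure_mode = c("estimate", "fixed"),
                       fixed_value = NA_real_) {
  structure_family <- match.arg(structure_family)
  structure_mode <- match.arg(structure_mode)
  if (!length(predictors)) stop("at least one predictor required")
  predictors <- match.arg(predictors, c("log10_mass", "log10_longevity"),
                          several.ok = TRUE)
  if (include_interaction && length(predictors) < 2L)
    stop("interaction requires both predictors")
  if (structure_mode == "fixed") {
    if (!is.finite(fixed_value)) stop("fixed structure_mode needs fixed_value")
    if (structure_family == "LAMBDA" && (fixed_value < 0 || fixed_value > 1))
      stop("fixed lambda must be in [0, 1]")
    if (structure_family == "OU" && fixed_value < 0) stop("fixed alpha must be >= 0")
  }
  structure(list(response = response, predictors = predictors,
                 include_interaction = include_interaction,
                 structure_family = structure_family,
                 structure_mode = structure_mode, fixed_value = fixed_value),
            class = "model_spec")
}

#' MCMC run settings
#'
#' Defaults follow the study design this package reproduces: at least 5000
#' iterations per chain with a 2000-iteration burn-in, thinning interval 5
#' and four chains. Draws are retained at burn_in + thin, burn_in + 2*thin,
#' ..., so each chain keeps `(iterations - burn_in) %/% thin` draws.
#'
#' @param iterations iterations per chain (default 5000).
#' @param burn_in discarded initial iterations (default 2000).
#' @param thin thinning interval (default 5).
#' @param chains number of chains, >= 2 (default 4).
#' @param seed integer RNG seed.
#' @return an `mcmc_config` object.
#' @export
mcmc_config <- function(iterations = 5000L, burn_in = 2000L, thin = 5L,
                        chains = 4L, seed = 1L) {
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin); chains <- as.integer(chains)
  if (iterations <= burn_in) stop("iterations must exceed burn_in")
  if (thin < 1L) stop("thin must be >= 1")
  if (chains < 2L) stop("at least 2 chains required")
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 chains = chains, seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Prior configuration
#'
#' The original analysis used sampler-default weakly-informative priors that
#' it did not enumerate; these documented stand-ins are proper and close to
#' those defaults: Normal(0, beta_sd) on regression coefficients,
#' half-Student-t(sigma_df, 0, sigma_scale) on the phylogenetic SD,
#' half-Normal(0, alpha_sd) on the OU rate (for a depth-1 tree), and
#' Uniform(0, 1) on Pagel's lambda.
#'
#' @param beta_sd SD of the Normal prior on coefficients (default 10).
#' @param sigma_df,sigma_scale half-Student-t parameters for sigma_phylo
#'   (defaults 3 and 2.5).
#' @param alpha_sd half-Normal scale for the OU alpha (default 5).
#' @return a `prior_config` object.
#' @export
prior_config <- function(beta_sd = 10, sigma_df = 3, sigma_scale = 2.5,
                         alpha_sd = 5) {
  stopifnot(beta_sd > 0, sigma_df > 0, sigma_scale > 0, alpha_sd > 0)
  structure(list(beta_sd = beta_sd, sigma_df = sigma_df,
                 sigma_scale = sigma_scale, alpha_sd = alpha_sd),
            class = "prior_config")
}

#' Design matrix for a model spec
#'
#' Column order: intercept, predictors in spec order, then the interaction
#' product if requested.
#'
#' @param dataset a `prevalence_dataset`.
#' @param spec a `model_spec`.
#' @return numeric matrix with named columns.
#' @export
design_matrix <- function(dataset, spec) {
  S <- n_species(dataset)
  cols <- list("(Intercept)" = rep(1, S))
  for (p in spec$predictors) {
    x <- dataset$covariates[[p]]
    if (is.null(x)) stop("dataset lacks covariate '", p, "'")
    cols[[p]] <- x
  }
  if (spec$include_interaction) {
    cols[["log10_mass:log10_longevity"]] <-
      dataset$covariates$log10_mass * dataset$covariates$log10_longevity
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  for (j in seq_len(ncol(X))[-1]) {
    if (var(X[, j]) < 1e-12) stop("zero-variance predictor: ", colnames(X)[j])
  }
  X
}

#' Binomial log-likelihood of the prevalence model
#'
#' Sum over species of log Binomial(k_i | n_i, inv_logit(eta_i)) with
#' eta_i = x_i' beta + u_i. The binomial coefficient is included so that
#' pointwise log-likelihoods are comparable across models in WAIC/LOO.
#'
#' @param beta coefficient vector aligned with [design_matrix()] columns.
#' @param u species random effects (logit scale), aligned to species order.
#' @param dataset a `prevalence_dataset`.
#' @param spec a `model_spec`.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(beta, u, dataset, spec) {
  X <- design_matrix(dataset, spec)
  if (length(beta) != ncol(X)) stop("beta length mismatch: expected ", ncol(X))
  if (length(u) != n_species(dataset)) stop("u length mismatch")
  k <- dataset$counts[[spec$response]]
  if (is.null(k)) stop("dataset has no count column '", spec$response, "'")
  eta <- drop(X %*% beta) + u
  sum(pointwise_binom_loglik(k, dataset$n_necropsies, eta))
}

# Stable binomial log-pmf on the logit scale, per species.
pointwise_binom_loglik <- function(k, n, eta) {
  # log p = -log1p(exp(-eta)); log(1-p) = -eta - log1p(exp(-eta))
  log1pexp <- function(x) ifelse(x > 35, x, log1p(exp(x)))
  lchoose(n, k) + k * (-log1pexp(-eta)) + (n - k) * (-eta - log1pexp(-eta))
}

#' Joint log-prior density
#'
#' Sum of the independent log prior densities of [prior_config()]. Values
#' outside the support (sigma < 0, lambda outside \[0,1\], alpha < 0) return
#' -Inf rather than erroring.
#'
#' @param beta coefficient vector.
#' @param sigma_phylo phylogenetic SD, >= 0.
#' @param structure_param OU alpha or Pagel's lambda, per `spec`.
#' @param spec a `model_spec`.
#' @param priors a `prior_config`.
#' @return scalar log-density (possibly -Inf).
#' @export
log_prior <- function(beta, sigma_phylo, structure_param, spec,
                      priors = prior_config()) {
  if (sigma_phylo < 0) return(-Inf)
  lp <- sum(stats::dnorm(beta, 0, priors$beta_sd, log = TRUE))
  # half-Student-t: 2 * t density on [0, Inf)
  lp <- lp + log(2) + stats::dt(sigma_phylo / priors$sigma_scale,
                                df = priors$sigma_df, log = TRUE) -
    log(priors$sigma_scale)
  if (spec$structure_family == "OU") {
    if (structure_param < 0) return(-Inf)
    lp <- lp + log(2) + stats::dnorm(structure_param, 0, priors$alpha_sd, log = TRUE)
  } else {
    if (structure_param < 0 || structure_param > 1) return(-Inf)
    # Uniform(0,1): density 1, contributes 0
  }
  lp
}
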