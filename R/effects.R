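#' Odds-ratio summary for one coefficient
#'
#' Quantiles are computed on the logit-scale draws and then exponentiated
#' (exp is monotone, so quantiles carry over). A slope is "significant" when
#' its 95% credible interval excludes 0 — equivalently the OR interval
#' excludes 1; the direction is the sign of the posterior median when
#' significant, 0 otherwise.
#'
#' @param fit a `posterior_fit` (or a numeric vector of coefficient draws).
#' @param coefficient coefficient name, e.g. `"log10_mass"` (ignored when
#'   `fit` is already a draw vector).
#' @return an `effect_summary` list: `coefficient`, `beta_median`,
#'   `beta_q` (2.5/25/50/75/97.5%), `or`, `or_q`, `significant`, `direction`.
#' @export
odds_ratio_summary <- function(fit, coefficient = NULL) {
  if (inherits(fit, "posterior_fit")) {
    if (is.null(coefficient)) stop("coefficient name required")
    draws <- pooled_draws(fit, coefficient)
  } else {
    draws <- as.numeric(fit)
    if (is.null(coefficient)) coefficient <- "coefficient"
  }
  probs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  bq <- quantile(draws, probs, names = FALSE)
  significant <- bq[1] > 0 || bq[5] < 0
  structure(list(coefficient = coefficient,
                 beta_median = bq[3],
                 beta_q = setNames(bq, paste0("q", probs * 100)),
                 or = exp(bq[3]),
                 or_q = setNames(exp(bq), paste0("q", probs * 100)),
                 significant = significant,
                 direction = if (significant) sign(bq[3]) else 0),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("%s: OR %.3f [%.3f, %.3f] %s\n", x$coefficient, x$or,
              x$or_q[["q2.5"]], x$or_q[["q97.5"]],
              if (x$significant) sprintf("significant (%+d)", x$direction)
              else "not significant"))
  invisible(x)
}

#' Marginal-effect curve of prevalence over one predictor
#'
#' For each posterior draw, the linear predictor is evaluated over a grid of
#' the focal predictor with every other covariate held at its in-sample mean
#' and the species effect set to 0 (population-level curve); prevalence is
#' the inverse-logit. Bands are central posterior quantile intervals at each
#' grid point (nested by construction).
#'
#' @param fit a `posterior_fit`.
#' @param dataset optional dataset for the grid range and covariate means
#'   (defaults to the fitted one).
#' @param predictor focal predictor name, present in the model.
#' @param grid_size number of grid points over the observed range (default 50).
#' @param levels central band levels in percent (default 50, 75, 95).
#' @return a `marginal_curve` data.frame: `predictor_value`, `median`, and
#'   `lo<level>`/`hi<level>` columns; attribute `predictor`.
#' @export
marginal_effect_curve <- function(fit, dataset = NULL, predictor,
                                  grid_size = 50L, levels = c(50, 75, 95)) {
  if (is.null(dataset)) dataset <- fit$dataset
  spec <- fit$spec
  if (!predictor %in% spec$predictors)
    stop("predictor '", predictor, "' not in the model")
  X <- design_matrix(dataset, spec)
  xobs <- dataset$covariates[[predictor]]
  grid <- seq(min(xobs), max(xobs), length.out = grid_size)
  others <- setdiff(spec$predictors, predictor)
  other_means <- vapply(others, function(p) mean(dataset$covariates[[p]]),
                        numeric(1))
  p_names <- colnames(X)
  beta <- vapply(p_names, function(pn) pooled_draws(fit, pn),
                 numeric(length(fit$lp)))
  # draw-by-grid linear predictor
  eta <- matrix(beta[, "(Intercept)"], nrow(beta), grid_size)
  eta <- eta + outer(beta[, predictor], grid)
  for (p in others) eta <- eta + beta[, p] * other_means[[p]]
  if (spec$include_interaction) {
    bint <- beta[, "log10_mass:log10_longevity"]
    eta <- eta + outer(bint, grid) * other_means[[others[1]]]
  }
  prev <- plogis(eta)
  med <- apply(prev, 2, median)
  out <- data.frame(predictor_value = grid, median = med)
  for (lv in sort(levels)) {
    a <- (1 - lv / 100) / 2
    out[[paste0("lo", lv)]] <- apply(prev, 2, quantile, probs = a)
    out[[paste0("hi", lv)]] <- apply(prev, 2, quantile, probs = 1 - a)
  }
  attr(out, "predictor") <- predictor
  class(out) <- c("marginal_curve", class(out))
  out
}

#' Jeffreys credible interval for a binomial proportion
#'
#' Central `level` interval of the Beta(k + 1/2, n - k + 1/2) posterior
#' (Jeffreys prior), with the conventional boundary rule: the lower limit is
#' 0 when k = 0 and the upper limit is 1 when k = n. Well suited to the
#' small necropsy counts (n <= 40) typical of comparative-oncology data.
#'
#' @param k number of cases (0 <= k <= n).
#' @param n number of necropsies (>= 1). `k` and `n` are recycled.
#' @param level central coverage (default 0.95).
#' @return data.frame with columns `lo` and `hi`.
#' @export
jeffreys_interval <- function(k, n, level = 0.95) {
  stopifnot(level > 0, level < 1)
  m <- max(length(k), length(n))
  k <- rep_len(as.numeric(k), m); n <- rep_len(as.numeric(n), m)
  if (any(n < 1)) stop("n must be >= 1")
  if (any(k < 0) || any(k > n)) stop("k must satisfy 0 <= k <= n")
  a <- (1 - level) / 2
  lo <- ifelse(k == 0, 0, qbeta(a, k + 0.5, n - k + 0.5))
  hi <- ifelse(k == n, 1, qbeta(1 - a, k + 0.5, n - k + 0.5))
  data.frame(lo = lo, hi = hi)
}

#' Expected credible-interval width versus sample size
#'
#' For each n on the grid, the exact expectation over k ~ Binomial(n, p_true)
#' of the Jeffreys interval width (summing over all k, no simulation). Shows
#' how necropsy counts drive prevalence uncertainty: widths shrink in n and,
#' for fixed n, peak at p_true = 0.5.
#'
#' @param p_true true prevalence in (0, 1).
#' @param n_grid increasing vector of sample sizes.
#' @param level interval level (default 0.95).
#' @return data.frame with columns `n` and `width`.
#' @export
ci_width_curve <- function(p_true, n_grid, level = 0.95) {
  if (p_true <= 0 || p_true >= 1) stop("p_true must be in (0, 1)")
  n_grid <- as.integer(n_grid)
  if (any(n_grid < 1)) stop("n_grid must be positive")
  widths <- vapply(n_grid, function(n) {
    kk <- 0:n
    ji <- jeffreys_interval(kk, n, level)
    sum(dbinom(kk, n, p_true) * (ji$hi - ji$lo))
  }, numeric(1))
  data.frame(n = n_grid, width = widths)
}

#' Tidy export of a marginal curve
#' @param curve a `marginal_curve`.
#' @param path output CSV path.
#' @export
write_curve_csv <- function(curve, path) {
  lv <- sort(as.integer(sub("^lo", "", grep("^lo", names(curve), value = TRUE))))
  rows <- do.call(rbind, lapply(lv, function(l) {
    data.frame(predictor_value = curve$predictor_value, level = l,
               lower = curve[[paste0("lo", l)]], median = curve$median,
               upper = curve[[paste0("hi", l)]])
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
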