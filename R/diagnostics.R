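#' Split-chain potential scale reduction factor (R-hat)
#'
#' Each chain is split in half before comparing between- and within-chain
#' variance, so trending single chains are caught. Constant chains return 1
#' with a warning (zero-within-variance convention).
#'
#' @param chains numeric matrix \[iteration, chain\] of draws for one
#'   parameter; at least 2 chains with 4 draws each.
#' @return scalar R-hat.
#' @export
split_rhat <- function(chains) {
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L || nrow(chains) < 4L)
    stop("need >= 2 chains with >= 4 draws each")
  sp <- split_chains(chains)
  if (all(apply(sp, 2, var) < .Machine$double.eps)) {
    warning("constant chains: R-hat defined as 1")
    return(1)
  }
  n <- nrow(sp); m <- ncol(sp)
  W <- mean(apply(sp, 2, var))
  B <- n * var(colMeans(sp))
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

split_chains <- function(chains) {
  n <- nrow(chains)
  h <- n %/% 2L
  cbind(chains[seq_len(h), , drop = FALSE],
        chains[(n - h + 1L):n, , drop = FALSE])
}

#' Effective sample size (bulk or tail)
#'
#' Bulk ESS rank-normalizes the pooled draws before computing the combined
#' autocorrelation ESS (Geyer initial monotone sequence over split chains);
#' tail ESS is the minimum of the ESS of the 5% and 95% quantile-exceedance
#' indicators. Values are capped at 1.5x the total draw count (antithetic
#' chains can exceed the nominal count; the cap keeps the gate conservative).
#' Constant chains return 0 with a warning.
#'
#' @param chains matrix \[iteration, chain\].
#' @param kind `"bulk"` or `"tail"`.
#' @return scalar ESS.
#' @export
ess <- function(chains, kind = c("bulk", "tail")) {
  kind <- match.arg(kind)
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L || nrow(chains) < 4L)
    stop("need >= 2 chains with >= 4 draws each")
  if (var(as.vector(chains)) < .Machine$double.eps) {
    warning("constant chains: ESS defined as 0")
    return(0)
  }
  if (kind == "bulk") {
    ess_base(rank_normalize(chains))
  } else {
    q <- quantile(as.vector(chains), c(0.05, 0.95), names = FALSE)
    e1 <- ess_base(1 * (chains <= q[1]))
    e2 <- ess_base(1 * (chains >= q[2]))
    min(e1, e2)
  }
}

rank_normalize <- function(chains) {
  d <- dim(chains)
  r <- rank(as.vector(chains), ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, d[1], d[2])
}

# combined-chain autocorrelation ESS with Geyer initial monotone sequence
ess_base <- function(chains) {
  sp <- split_chains(as.matrix(chains))
  n <- nrow(sp); m <- ncol(sp)
  if (all(apply(sp, 2, var) < .Machine$double.eps)) return(0)
  acov <- apply(sp, 2, function(x) {
    a <- acf(x, lag.max = n - 1L, type = "covariance", plot = FALSE,
             demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  })
  acov <- as.matrix(acov)
  W <- mean(acov[1, ]) * n / (n - 1)
  mean_var <- mean(acov[1, ])
  B_over_n <- if (m > 1) var(colMeans(sp)) else 0
  var_plus <- mean_var * n / (n - 1) + B_over_n
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  rho[1] <- 1
  # Geyer: paired sums, keep while positive, enforce monotone decrease
  max_t <- floor((n - 1) / 2)
  tau <- 1
  prev_pair <- Inf
  for (t in seq_len(max_t)) {
    pair <- rho[2 * t] + rho[2 * t + 1]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev_pair)
    prev_pair <- pair
    tau <- tau + 2 * pair
  }
  N <- n * m
  min(N / tau, 1.5 * N)
}

#' Mean lag-k autocorrelation across chains
#' @param chains matrix \[iteration, chain\].
#' @param lag lag (default 1, applied to the thinned retained draws).
#' @return scalar autocorrelation.
#' @export
lag_autocorr <- function(chains, lag = 1L) {
  chains <- as.matrix(chains)
  vals <- apply(chains, 2, function(x) {
    if (var(x) < .Machine$double.eps) return(0)
    acf(x, lag.max = lag, plot = FALSE, demean = TRUE)$acf[lag + 1L, 1, 1]
  })
  mean(vals)
}

#' Convergence report for a fitted model
#'
#' Applies the convergence gates used throughout: |R-hat - 1| <= `rhat_tol`
#' for every parameter, bulk and tail ESS > `ess_min`, and |lag-1
#' autocorrelation| of the thinned retained draws < `ac_max`.
#'
#' @param fit a `posterior_fit`.
#' @param rhat_tol R-hat tolerance around 1 (default 0.01).
#' @param ess_min ESS threshold (default 1000).
#' @param ac_max lag-1 autocorrelation bound (default 0.1).
#' @return a `convergence_report`: per-parameter data.frame plus `pass` flag.
#' @export
convergence_report <- function(fit, rhat_tol = 0.01, ess_min = 1000,
                               ac_max = 0.1) {
  rows <- lapply(fit$parameters, function(p) {
    ch <- chain_draws(fit, p)
    constant <- var(as.vector(ch)) < .Machine$double.eps
    data.frame(parameter = p,
               rhat = if (constant) 1 else split_rhat(ch),
               ess_bulk = suppressWarnings(ess(ch, "bulk")),
               ess_tail = suppressWarnings(ess(ch, "tail")),
               lag1_autocorr = lag_autocorr(ch))
  })
  tab <- do.call(rbind, rows)
  pass <- all(abs(tab$rhat - 1) <= rhat_tol) &&
    all(tab$ess_bulk > ess_min) && all(tab$ess_tail > ess_min) &&
    all(abs(tab$lag1_autocorr) < ac_max)
  structure(list(table = tab, pass = pass, rhat_tol = rhat_tol,
                 ess_min = ess_min, ac_max = ac_max),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("convergence_report:", if (x$pass) "PASS" else "FAIL", "\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Widely applicable information criterion (WAIC)
#'
#' `lppd_i = log mean_s exp(ll_si)` (log-sum-exp stabilized),
#' `p_i = var_s(ll_si)`, `waic = -2 * sum(lppd_i - p_i)`.
#'
#' @param pointwise_loglik draws x species matrix of pointwise
#'   log-likelihoods, or a `posterior_fit`.
#' @return list with `waic`, `p_waic`, `se_waic`, `elpd_i`, `p_i`.
#' @export
waic <- function(pointwise_loglik) {
  ll <- as_ll_matrix(pointwise_loglik)
  Sdraws <- nrow(ll)
  lppd <- apply(ll, 2, logsumexp) - log(Sdraws)
  p_i <- apply(ll, 2, var)
  pointwise <- -2 * (lppd - p_i)
  list(waic = sum(pointwise), p_waic = sum(p_i),
       se_waic = sqrt(ncol(ll) * var(pointwise)),
       elpd_i = lppd - p_i, p_i = p_i)
}

as_ll_matrix <- function(x) {
  if (inherits(x, "posterior_fit")) x <- x$pointwise_loglik
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("pointwise log-likelihood has non-finite entries")
  x
}

# Zhang & Stephens (2009) empirical-Bayes generalized-Pareto fit to
# exceedances x > 0; returns shape xi (Vehtari's k: > 0 means heavy tail).
gpd_fit <- function(x) {
  x <- sort(x)
  N <- length(x)
  if (N < 5L || x[N] <= 0) return(list(xi = -Inf, sigma = NA_real_))
  M <- 30L + floor(sqrt(N))
  jj <- seq_len(M)
  xstar <- x[max(1L, floor(N / 4 + 0.5))]
  b <- 1 / x[N] + (1 - sqrt(M / (jj - 0.5))) / (3 * xstar)
  prof <- vapply(b, function(bj) {
    kk <- -mean(log1p(-bj * x))
    if (!is.finite(kk) || kk == 0 || bj / kk <= 0) return(-Inf)
    N * (log(bj / kk) + kk - 1)
  }, numeric(1))
  if (all(!is.finite(prof))) return(list(xi = -Inf, sigma = NA_real_))
  w <- exp(prof - max(prof))
  w <- w / sum(w)
  b_hat <- sum(b * w)
  k_zs <- -mean(log1p(-b_hat * x))
  xi <- -k_zs
  sigma <- k_zs / b_hat
  list(xi = xi, sigma = sigma)
}

qgpd <- function(p, xi, sigma) {
  if (abs(xi) < 1e-12) return(-sigma * log1p(-p))
  sigma * ((1 - p)^(-xi) - 1) / xi
}

#' Pareto-smoothed importance-sampling leave-one-out criterion (PSIS-LOO)
#'
#' Per species, the raw importance weights are exp(-ll_si); a generalized
#' Pareto distribution is fitted to the top 20% of weights and the tail is
#' replaced by its expected order statistics (capped at the raw maximum).
#' Species whose pointwise log-likelihood is constant across draws get the
#' degenerate-weight convention `pareto_k = -Inf` and exact elpd.
#'
#' @inheritParams waic
#' @param tail_frac fraction of draws treated as the weight tail (default 0.2).
#' @return list with `looic`, `elpd_loo`, `pareto_k` (per species),
#'   `n_high_k` (count of k > 0.7).
#' @export
psis_loo <- function(pointwise_loglik, tail_frac = 0.2) {
  ll <- as_ll_matrix(pointwise_loglik)
  Sdraws <- nrow(ll)
  if (Sdraws < 100L)
    warning("fewer than 100 draws: PSIS-LOO tail fit is unreliable")
  res <- apply(ll, 2, function(lli) {
    lw <- -lli
    lw <- lw - max(lw)
    if (sd(lli) < 1e-12) {
      return(c(elpd = lli[1], k = -Inf))
    }
    w <- exp(lw)
    M <- ceiling(tail_frac * Sdraws)
    ord <- order(w)
    cut_idx <- ord[Sdraws - M]
    u <- w[cut_idx]
    tail_idx <- ord[(Sdraws - M + 1L):Sdraws]
    exc <- w[tail_idx] - u
    fit <- gpd_fit(exc)
    k <- fit$xi
    if (is.finite(k) && !is.na(fit$sigma) && fit$sigma > 0) {
      sm <- u + qgpd((seq_len(M) - 0.5) / M, fit$xi, fit$sigma)
      sm <- pmin(sm, max(w))
      w[tail_idx[order(w[tail_idx])]] <- sort(sm)
    }
    lw_s <- log(w)
    lw_s <- lw_s - logsumexp(lw_s)
    c(elpd = logsumexp(lli + lw_s), k = k)
  })
  elpd <- res["elpd", ]
  k <- res["k", ]
  list(looic = -2 * sum(elpd), elpd_loo = elpd, pareto_k = k,
       n_high_k = sum(is.finite(k) & k > 0.7))
}

#' Combined information-criterion report for a fit
#' @param fit a `posterior_fit` (or pointwise log-likelihood matrix).
#' @return an `ic_report` list: waic, p_waic, se_waic, looic, pareto_k,
#'   n_high_k.
#' @export
ic_report <- function(fit) {
  w <- waic(fit)
  l <- suppressWarnings(psis_loo(fit))
  structure(list(waic = w$waic, p_waic = w$p_waic, se_waic = w$se_waic,
                 looic = l$looic, pareto_k = l$pareto_k,
                 n_high_k = l$n_high_k),
            class = "ic_report")
}

#' @export
print.ic_report <- function(x, ...) {
  cat(sprintf("WAIC %.2f (p_waic %.2f, se %.2f)  LOOIC %.2f  [k > 0.7: %d]\n",
              x$waic, x$p_waic, x$se_waic, x$looic, x$n_high_k))
  invisible(x)
}

#' Compare OU and Pagel's-lambda covariance structures for the same model
#'
#' The preferred structure is the one with lower WAIC. Differences are signed
#' lambda minus OU, so positive deltas favour OU. Absolute WAIC differences
#' below 2 are flagged indistinguishable but still resolved by the lower
#' value.
#'
#' @param fit_ou `posterior_fit` with OU structure.
#' @param fit_lambda `posterior_fit` with LAMBDA structure, same data,
#'   response and predictors.
#' @return list: `preferred`, `delta_waic`, `delta_looic`, `indistinguishable`.
#' @export
compare_structures <- function(fit_ou, fit_lambda) {
  stopifnot(inherits(fit_ou, "posterior_fit"), inherits(fit_lambda, "posterior_fit"))
  if (fit_ou$spec$structure_family != "OU" ||
      fit_lambda$spec$structure_family != "LAMBDA")
    stop("expected one OU fit and one LAMBDA fit, in that order")
  if (fit_ou$data_hash != fit_lambda$data_hash ||
      fit_ou$spec$response != fit_lambda$spec$response ||
      !identical(fit_ou$spec$predictors, fit_lambda$spec$predictors))
    stop("fits are not on the same data/response/predictors")
  w_ou <- waic(fit_ou)$waic
  w_la <- waic(fit_lambda)$waic
  l_ou <- suppressWarnings(psis_loo(fit_ou))$looic
  l_la <- suppressWarnings(psis_loo(fit_lambda))$looic
  delta <- w_la - w_ou
  list(preferred = if (w_ou <= w_la) "OU" else "LAMBDA",
       delta_waic = delta, delta_looic = l_la - l_ou,
       indistinguishable = abs(delta) < 2)
}

#' Posterior predictive check with randomized-quantile (PIT) residuals
#'
#' For each species the PIT residual is drawn uniformly between
#' F(k_i - 1) and F(k_i), where F is the posterior-predictive binomial CDF
#' averaged over draws. Under a well-specified model the residuals are
#' uniform on \[0, 1\]; uniformity is tested by Kolmogorov-Smirnov. Summary
#' statistics compare observed and replicated zero counts and maximum
#' prevalence.
#'
#' @param fit a `posterior_fit`.
#' @param dataset optionally a different `prevalence_dataset` (defaults to
#'   the fitted one).
#' @param seed RNG seed for the residual randomization.
#' @param max_draws cap on the posterior draws used (default 1000).
#' @return list: `pit`, `uniformity_p`, `summary`.
#' @export
posterior_predictive_check <- function(fit, dataset = NULL, seed = 1L,
                                       max_draws = 1000L) {
  if (is.null(dataset)) dataset <- fit$dataset
  k <- dataset$counts[[fit$spec$response]]
  n <- dataset$n_necropsies
  X <- design_matrix(dataset, fit$spec)
  p_names <- colnames(X)
  beta <- vapply(p_names, function(pn) pooled_draws(fit, pn),
                 numeric(length(fit$lp)))
  nd <- nrow(beta)
  use <- if (nd > max_draws) round(seq(1, nd, length.out = max_draws)) else seq_len(nd)
  eta <- tcrossprod(beta[use, , drop = FALSE], X) + fit$u[use, , drop = FALSE]
  pmatrix <- plogis(eta) # draws x species
  set.seed(seed)
  S <- length(k)
  pit <- numeric(S)
  flagged <- logical(S)
  for (i in seq_len(S)) {
    Fk <- mean(pbinom(k[i], n[i], pmatrix[, i]))
    Fkm1 <- if (k[i] > 0) mean(pbinom(k[i] - 1L, n[i], pmatrix[, i])) else 0
    if (Fk - Fkm1 < 1e-12) {
      pit[i] <- min(max(Fk, 0), 1)
      flagged[i] <- TRUE
    } else {
      pit[i] <- runif(1, Fkm1, Fk)
    }
  }
  upv <- if (S >= 2) suppressWarnings(ks.test(pit, "punif")$p.value) else NA_real_
  rep_idx <- use[seq_len(min(500L, length(use)))]
  k_rep <- matrix(rbinom(length(rep_idx) * S, size = rep(n, each = length(rep_idx)),
                         prob = pmatrix[seq_along(rep_idx), ]),
                  nrow = length(rep_idx))
  list(pit = pit, uniformity_p = upv, degenerate = flagged,
       summary = list(zeros_obs = sum(k == 0),
                      zeros_rep_mean = mean(rowSums(k_rep == 0)),
                      max_prev_obs = max(k / n),
                      max_prev_rep_mean = mean(apply(sweep(k_rep, 2, n, "/"), 1, max))))
}
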