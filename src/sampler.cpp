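// Adaptive Metropolis-within-Gibbs sampler for the binomial phylogenetic
// prevalence regression with non-centred species effects u = sigma * L(theta) * z.
// One call runs one chain; R drives seeding and chain stacking.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double log1p_exp(double x) {
  return (x > 35.0) ? x : std::log1p(std::exp(x));
}

// pointwise binomial log-pmf on the logit scale (lchoose precomputed)
static void pointwise_ll(const arma::vec& k, const arma::vec& n,
                         const arma::vec& lch, const arma::vec& eta,
                         arma::vec& out) {
  const arma::uword S = k.n_elem;
  for (arma::uword i = 0; i < S; ++i) {
    double l1 = log1p_exp(-eta[i]);
    out[i] = lch[i] - k[i] * l1 + (n[i] - k[i]) * (-eta[i] - l1);
  }
}

static double sum_ll(const arma::vec& k, const arma::vec& n,
                     const arma::vec& lch, const arma::vec& eta) {
  double s = 0.0;
  const arma::uword S = k.n_elem;
  for (arma::uword i = 0; i < S; ++i) {
    double l1 = log1p_exp(-eta[i]);
    s += lch[i] - k[i] * l1 + (n[i] - k[i]) * (-eta[i] - l1);
  }
  return s;
}

// correlation matrix from shared-path times; family 0 = OU, 1 = LAMBDA
static arma::mat build_corr(const arma::mat& tmat, double depth,
                            int family, double param) {
  arma::mat R;
  if (family == 0) { // OU, BM limit for tiny alpha
    if (param <= 1e-8) {
      R = tmat / depth;
    } else {
      double denom = 1.0 - std::exp(-2.0 * param * depth);
      R = arma::exp(-2.0 * param * (depth - tmat)) %
          (1.0 - arma::exp(-2.0 * param * tmat)) / denom;
    }
  } else { // Pagel's lambda
    R = param * tmat / depth;
  }
  R.diag().ones();
  return R;
}

// lower Cholesky with diagonal jitter ladder; returns false if all fail
static bool chol_jitter(const arma::mat& R, arma::mat& L) {
  if (arma::chol(L, R, "lower")) return true;
  for (int e = -10; e <= -6; ++e) {
    arma::mat Rj = R;
    Rj.diag() += std::pow(10.0, e);
    if (arma::chol(L, Rj, "lower")) return true;
  }
  return false;
}

static inline double lp_beta(const arma::vec& beta, double beta_sd) {
  double s = 0.0;
  for (arma::uword j = 0; j < beta.n_elem; ++j)
    s += R::dnorm(beta[j], 0.0, beta_sd, 1);
  return s;
}

// log prior of log(sigma) including Jacobian (half-t on sigma)
static inline double lp_lsigma(double ls, double df, double scale) {
  double sigma = std::exp(ls);
  return M_LN2 + R::dt(sigma / scale, df, 1) - std::log(scale) + ls;
}

// log prior of transformed structure parameter including Jacobian
static inline double lp_theta(double theta, int family, double alpha_sd) {
  if (family == 0) { // theta = log(alpha), half-Normal(0, alpha_sd) on alpha
    double a = std::exp(theta);
    return M_LN2 + R::dnorm(a, 0.0, alpha_sd, 1) + theta;
  }
  // theta = logit(lambda), Uniform(0,1) on lambda
  double lam = 1.0 / (1.0 + std::exp(-theta));
  return std::log(lam) + std::log1p(-lam);
}

static inline double nat_param(double theta, int family) {
  return (family == 0) ? std::exp(theta) : 1.0 / (1.0 + std::exp(-theta));
}

// [[Rcpp::export(name = ".mwg_chain")]]
List mwg_chain(const arma::vec& k, const arma::vec& n, const arma::mat& X,
               const arma::mat& tmat, double depth,
               int family, bool estimate_structure, double init_param,
               int iterations, int burn_in, int thin,
               double beta_sd, double sigma_df, double sigma_scale,
               double alpha_sd,
               bool fix_sigma, double sigma_fixed,
               const arma::vec& beta_init) {
  const arma::uword S = k.n_elem, p = X.n_cols;
  arma::vec lch(S);
  for (arma::uword i = 0; i < S; ++i) lch[i] = R::lchoose(n[i], k[i]);

  // state
  arma::vec beta = beta_init;
  double ls = fix_sigma ? (sigma_fixed > 0 ? std::log(sigma_fixed) : -25.0)
                        : std::log(0.5);
  double theta;
  if (family == 0) theta = std::log(std::max(init_param, 1e-3));
  else {
    double lam = std::min(std::max(init_param, 1e-3), 1.0 - 1e-3);
    theta = std::log(lam / (1.0 - lam));
  }
  arma::vec z(S, arma::fill::zeros);

  arma::mat L;
  if (!chol_jitter(build_corr(tmat, depth, family, nat_param(theta, family)), L))
    stop("correlation matrix not positive definite after jitter");

  double sigma = fix_sigma ? sigma_fixed : std::exp(ls);
  arma::vec Xbeta = X * beta;
  arma::vec Lz = L * z;
  arma::vec u = sigma * Lz;
  arma::vec eta = Xbeta + u;
  double cur_ll = sum_ll(k, n, lch, eta);

  // adaptive log proposal scales (target acceptance 0.44)
  arma::vec lsc_beta(p); lsc_beta.fill(std::log(0.2));
  double lsc_ls = std::log(0.3), lsc_th = std::log(0.5);
  arma::vec lsc_z(S); lsc_z.fill(std::log(0.8));
  const double target = 0.44;

  const int n_keep = (iterations - burn_in) / thin;
  arma::mat beta_draws(n_keep, p), u_draws(n_keep, S), ll_draws(n_keep, S);
  arma::vec sigma_draws(n_keep), param_draws(n_keep), lp_draws(n_keep);
  arma::vec ll_tmp(S);
  int kept = 0;
  int acc_theta = 0, prop_theta = 0;

  for (int it = 1; it <= iterations; ++it) {
    double gam = std::pow((double)it, -0.6);
    bool adapting = it <= burn_in;

    // --- beta, scalar random-walk per coordinate ---
    for (arma::uword j = 0; j < p; ++j) {
      double db = std::exp(lsc_beta[j]) * R::norm_rand();
      arma::vec eta_p = eta + X.col(j) * db;
      double new_ll = sum_ll(k, n, lch, eta_p);
      double bj = beta[j] + db;
      double dlp = new_ll - cur_ll +
        R::dnorm(bj, 0.0, beta_sd, 1) - R::dnorm(beta[j], 0.0, beta_sd, 1);
      double a = std::min(1.0, std::exp(dlp));
      if (R::unif_rand() < a) {
        beta[j] = bj; eta = eta_p; Xbeta += X.col(j) * db; cur_ll = new_ll;
      }
      if (adapting) lsc_beta[j] = std::min(3.0, std::max(-10.0, lsc_beta[j] + gam * (a - target)));
    }

    if (!fix_sigma) {
      // --- log sigma ---
      double lsp = ls + std::exp(lsc_ls) * R::norm_rand();
      double sig_p = std::exp(lsp);
      arma::vec eta_p = Xbeta + sig_p * Lz;
      double new_ll = sum_ll(k, n, lch, eta_p);
      double dlp = new_ll - cur_ll +
        lp_lsigma(lsp, sigma_df, sigma_scale) - lp_lsigma(ls, sigma_df, sigma_scale);
      double a = std::min(1.0, std::exp(dlp));
      if (R::unif_rand() < a) {
        ls = lsp; sigma = sig_p; u = sigma * Lz; eta = Xbeta + u; cur_ll = new_ll;
      }
      if (adapting) lsc_ls = std::min(3.0, std::max(-10.0, lsc_ls + gam * (a - target)));
    }

    if (estimate_structure) {
      // --- structure parameter (transformed scale) ---
      ++prop_theta;
      double thp = theta + std::exp(lsc_th) * R::norm_rand();
      arma::mat Lp;
      double a = 0.0;
      if (chol_jitter(build_corr(tmat, depth, family, nat_param(thp, family)), Lp)) {
        arma::vec Lz_p = Lp * z;
        arma::vec eta_p = Xbeta + sigma * Lz_p;
        double new_ll = sum_ll(k, n, lch, eta_p);
        double dlp = new_ll - cur_ll +
          lp_theta(thp, family, alpha_sd) - lp_theta(theta, family, alpha_sd);
        a = std::min(1.0, std::exp(dlp));
        if (R::unif_rand() < a) {
          theta = thp; L = Lp; Lz = Lz_p; u = sigma * Lz; eta = Xbeta + u;
          cur_ll = new_ll; ++acc_theta;
        }
      }
      if (adapting) lsc_th = std::min(3.0, std::max(-10.0, lsc_th + gam * (a - target)));
    }

    if (!(fix_sigma && sigma_fixed <= 0.0)) {
      // --- species effects, elementwise on the non-centred scale ---
      for (arma::uword j = 0; j < S; ++j) {
        double dz = std::exp(lsc_z[j]) * R::norm_rand();
        double zj = z[j] + dz;
        // column j of lower-triangular L touches rows j..S-1
        arma::vec eta_p = eta;
        for (arma::uword i = j; i < S; ++i) eta_p[i] += sigma * L(i, j) * dz;
        double new_ll = sum_ll(k, n, lch, eta_p);
        double dlp = new_ll - cur_ll - 0.5 * (zj * zj - z[j] * z[j]);
        double a = std::min(1.0, std::exp(dlp));
        if (R::unif_rand() < a) {
          z[j] = zj;
          for (arma::uword i = j; i < S; ++i) {
            Lz[i] += L(i, j) * dz;
            u[i] = sigma * Lz[i];
          }
          eta = eta_p; cur_ll = new_ll;
        }
        if (adapting) lsc_z[j] = std::min(3.0, std::max(-10.0, lsc_z[j] + gam * (a - target)));
      }
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      beta_draws.row(kept) = beta.t();
      sigma_draws[kept] = sigma;
      param_draws[kept] = nat_param(theta, family);
      u_draws.row(kept) = u.t();
      pointwise_ll(k, n, lch, eta, ll_tmp);
      ll_draws.row(kept) = ll_tmp.t();
      double lp = cur_ll + lp_beta(beta, beta_sd) - 0.5 * arma::dot(z, z);
      if (!fix_sigma) lp += lp_lsigma(ls, sigma_df, sigma_scale);
      if (estimate_structure) lp += lp_theta(theta, family, alpha_sd);
      lp_draws[kept] = lp;
      ++kept;
    }
  }

  return List::create(
    _["beta"] = beta_draws, _["sigma"] = sigma_draws,
    _["param"] = param_draws, _["u"] = u_draws,
    _["pointwise_loglik"] = ll_draws, _["lp"] = lp_draws,
    _["accept_theta"] = prop_theta > 0 ? (double)acc_theta / prop_theta : NA_REAL);
}
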