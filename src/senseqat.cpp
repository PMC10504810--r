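// Core numerical routines: spike-and-slab Gibbs sampler and all-subsets
// dominance decomposition. Both use R's RNG stream so that results are
// bit-reproducible under set.seed() on the R side.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Gibbs sampler for the George-McCulloch continuous spike-and-slab model:
//   y = X beta + eps,  eps ~ N(0, sigma2 I)
//   beta_j | gamma_j ~ N(0, slab_sd^2) if gamma_j = 1, else N(0, spike_sd^2)
//   gamma_j ~ Bernoulli(prior_inclusion),  sigma2 ~ InvGamma(a0, b0)
// Predictors are swept in fixed order 1..p each iteration; within each j the
// indicator is updated given the current coefficient, then the coefficient
// given the indicator. X and y must already be standardized.
// [[Rcpp::export]]
List ssvs_gibbs_cpp(const arma::mat& X, const arma::vec& y,
                    double prior_inclusion, double spike_sd, double slab_sd,
                    double a0, double b0, int total_iter, int burn_in) {
  const int n = X.n_rows;
  const int p = X.n_cols;
  const int n_keep = total_iter - burn_in;

  arma::vec xtx(p);
  for (int j = 0; j < p; ++j) xtx(j) = arma::dot(X.col(j), X.col(j));

  arma::vec beta(p, arma::fill::zeros);
  arma::ivec gam(p, arma::fill::ones);
  double sigma2 = 1.0;
  arma::vec resid = y;  // y - X beta, maintained incrementally

  arma::imat gamma_keep(n_keep, p);
  arma::mat beta_keep(n_keep, p);
  arma::vec sigma2_keep(n_keep);

  const double lodds_prior =
      std::log(prior_inclusion) - std::log1p(-prior_inclusion);

  for (int it = 0; it < total_iter; ++it) {
    for (int j = 0; j < p; ++j) {
      const double b_old = beta(j);
      // indicator given coefficient: spike vs slab density ratio
      const double lo = lodds_prior +
          R::dnorm(b_old, 0.0, slab_sd, 1) - R::dnorm(b_old, 0.0, spike_sd, 1);
      const double pj = 1.0 / (1.0 + std::exp(-lo));
      gam(j) = (unif_rand() < pj) ? 1 : 0;

      // coefficient given indicator (conjugate normal update)
      const double tau2 = gam(j) ? slab_sd * slab_sd : spike_sd * spike_sd;
      const double v = 1.0 / (xtx(j) / sigma2 + 1.0 / tau2);
      // x_j' (y - X_{-j} beta_{-j}) from the maintained full residual
      const double xr = arma::dot(X.col(j), resid) + xtx(j) * b_old;
      const double b_new = v * xr / sigma2 + std::sqrt(v) * norm_rand();
      resid += X.col(j) * (b_old - b_new);
      beta(j) = b_new;
    }

    const double rss = arma::dot(resid, resid);
    sigma2 = 1.0 / R::rgamma(a0 + 0.5 * n, 1.0 / (b0 + 0.5 * rss));
    if (!std::isfinite(sigma2) || sigma2 <= 0.0)
      stop("residual variance became non-finite during sampling");

    if (it >= burn_in) {
      const int k = it - burn_in;
      for (int j = 0; j < p; ++j) gamma_keep(k, j) = gam(j);
      beta_keep.row(k) = beta.t();
      sigma2_keep(k) = sigma2;
    }
  }

  arma::vec mip(p);
  for (int j = 0; j < p; ++j)
    mip(j) = arma::mean(arma::conv_to<arma::vec>::from(gamma_keep.col(j)));

  return List::create(_["mip"] = mip,
                      _["gamma"] = gamma_keep,
                      _["beta"] = beta_keep,
                      _["sigma2"] = sigma2_keep);
}

// Squared multiple correlations for every predictor subset, from a
// correlation matrix with the outcome in the LAST row/column. Entry m of the
// returned vector is R^2 for the subset whose bitmask is m (bit j set =
// predictor j included); entry 0 (empty subset) is 0. Singular subsets fall
// back to the Moore-Penrose pseudoinverse.
// [[Rcpp::export]]
arma::vec all_subsets_r2_cpp(const arma::mat& R) {
  const int p = R.n_rows - 1;
  if (p < 1) stop("correlation matrix must include at least one predictor");
  if (p > 20) stop("subset enumeration is limited to 20 predictors");

  const arma::mat Rxx = R.submat(0, 0, p - 1, p - 1);
  const arma::vec rxy = R.submat(0, p, p - 1, p);

  const int nsub = 1 << p;
  arma::vec r2(nsub, arma::fill::zeros);
  std::vector<arma::uword> idx;
  idx.reserve(p);

  for (int m = 1; m < nsub; ++m) {
    idx.clear();
    for (int j = 0; j < p; ++j)
      if (m & (1 << j)) idx.push_back(static_cast<arma::uword>(j));
    const arma::uvec u(idx);
    const arma::mat Rs = Rxx.submat(u, u);
    const arma::vec rs = rxy.elem(u);
    arma::vec sol;
    const bool ok = arma::solve(sol, Rs, rs,
                                arma::solve_opts::no_approx + arma::solve_opts::likely_sympd);
    if (!ok) sol = arma::pinv(Rs) * rs;
    r2(m) = arma::dot(rs, sol);
  }
  return r2;
}

// General dominance weights: for predictor j, the incremental R^2 of adding
// j is averaged over all subsets of the other predictors of a given size,
// then averaged across the p subset sizes. Weights sum to the full-model R^2.
// [[Rcpp::export]]
List dominance_weights_cpp(const arma::mat& R) {
  const int p = R.n_rows - 1;
  const arma::vec r2 = all_subsets_r2_cpp(R);
  const int nsub = 1 << p;

  arma::vec w(p, arma::fill::zeros);
  arma::vec sums(p), cnts(p);
  for (int j = 0; j < p; ++j) {
    sums.zeros();
    cnts.zeros();
    const int bit = 1 << j;
    for (int m = 0; m < nsub; ++m) {
      if (m & bit) continue;
      int k = 0;  // popcount of m
      for (int t = m; t; t &= t - 1) ++k;
      sums(k) += r2(m | bit) - r2(m);
      cnts(k) += 1.0;
    }
    double wj = 0.0;
    for (int k = 0; k < p; ++k) wj += sums(k) / cnts(k);
    w(j) = wj / p;
  }

  return List::create(_["weights"] = w, _["r2_full"] = r2(nsub - 1));
}
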