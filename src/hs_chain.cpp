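// Core MCMC chain for the regularized-horseshoe marker model.
// Mirrors the R reference implementation (R/horseshoe.R, run_hs_chain_r):
// conjugate Gaussian block for beta, conjugate inverse-gamma for sigma^2,
// slice updates on log local/global/slab scales, a non-centered rescale
// move for tau, a non-centered per-coordinate move for lambda, and a
// pairwise swap move between tightly correlated markers. All randomness
// comes from R's RNG so runs are reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double log1p_e2u(double u) {
  return u > 0 ? 2.0 * u + std::log1p(std::exp(-2.0 * u))
               : std::log1p(std::exp(2.0 * u));
}

// tau^2 * lambda_tilde_j^2 = 1 / (exp(-2 loglam)/tau^2 + 1/c^2)
static inline double prior_var(double loglam, double tau2, double c2) {
  return 1.0 / (std::exp(-2.0 * loglam) / tau2 + 1.0 / c2);
}

// scalar slice sampler (stepping out + shrinkage)
template <typename F>
static double slice1(double u0, F logf, double w, int max_step = 30) {
  double z = logf(u0) - exp_rand();
  double lo = u0 - unif_rand() * w;
  double hi = lo + w;
  for (int i = 0; i < max_step && logf(lo) > z; ++i) lo -= w;
  for (int i = 0; i < max_step && logf(hi) > z; ++i) hi += w;
  for (int i = 0; i < 200; ++i) {
    double prop = lo + unif_rand() * (hi - lo);
    if (logf(prop) >= z) return prop;
    if (prop < u0) lo = prop; else hi = prop;
  }
  return u0;
}

// [[Rcpp::export(name = ".hs_chain_cpp")]]
List hs_chain_cpp(const arma::mat& X, const arma::vec& y, double tau0,
                  int warmup, int iter, double slab_df, double slab_s2,
                  bool sample_c2, double c2_init, bool sample_s2,
                  double s2_init, bool use_intercept, double a_sigma,
                  double b_sigma, IntegerVector swap_i, IntegerVector swap_j,
                  NumericVector swap_g) {
  const int n = X.n_rows, D = X.n_cols;
  const bool d_path = (double)D <= 2.1 * n;
  arma::mat XtX;
  if (d_path) XtX = X.t() * X;
  arma::vec xtx_diag = arma::sum(arma::square(X), 0).t();
  const double log_tau0 = std::log(tau0);

  arma::vec beta(D, arma::fill::zeros);
  arma::vec log_lambda(D, arma::fill::zeros);
  double log_tau = log_tau0;
  double c2 = c2_init, sigma2 = s2_init, b0 = 0.0;

  arma::mat out_beta(iter, D);
  arma::mat out_scal(iter, 4);
  arma::vec fitted(n, arma::fill::zeros), resid(n);
  const int npairs = swap_i.size();

  for (int it = 0; it < warmup + iter; ++it) {
    const double tau2 = std::exp(2.0 * log_tau);
    arma::vec v(D);
    for (int j = 0; j < D; ++j) v[j] = prior_var(log_lambda[j], tau2, c2);

    arma::vec r = y - b0;
    // ---- beta | scales: ridge conditional
    if (d_path) {
      arma::mat A = XtX / sigma2;
      A.diag() += 1.0 / v;
      arma::mat R;
      if (!arma::chol(R, A)) stop("Cholesky failure in coefficient update");
      arma::vec b = X.t() * r / sigma2;
      arma::vec m = arma::solve(arma::trimatu(R),
                                arma::solve(arma::trimatl(R.t()), b));
      arma::vec z(D);
      for (int j = 0; j < D; ++j) z[j] = norm_rand();
      beta = m + arma::solve(arma::trimatu(R), z);
    } else {
      arma::vec u(D), delta(n);
      for (int j = 0; j < D; ++j) u[j] = norm_rand() * std::sqrt(v[j]);
      for (int i = 0; i < n; ++i) delta[i] = norm_rand();
      const double s = std::sqrt(sigma2);
      arma::vec vv = X * u / s + delta;
      arma::mat Phi = X * arma::diagmat(v) * X.t() / sigma2;
      Phi.diag() += 1.0;
      arma::vec w = arma::solve(Phi, r / s - vv, arma::solve_opts::likely_sympd);
      beta = u + v % (X.t() * w) / s;
    }
    if (!beta.is_finite())
      stop("non-finite coefficient draw at iteration %d; chain aborted", it + 1);
    fitted = X * beta;

    // ---- intercept and residual variance
    if (use_intercept)
      b0 = arma::mean(y - fitted) + norm_rand() * std::sqrt(sigma2 / n);
    resid = y - b0 - fitted;
    if (sample_s2) {
      double shape = a_sigma + 0.5 * n;
      double rate = b_sigma + 0.5 * arma::dot(resid, resid);
      sigma2 = 1.0 / R::rgamma(shape, 1.0 / rate);
    }

    // The scale block (collapsed local scales, global scale, slab,
    // interweaved tau) is repeated several times per coefficient-block
    // draw: it costs a small fraction of the beta update and the
    // global scale is the slowest-mixing coordinate otherwise.
    for (int sweep = 0; sweep < 4; ++sweep) {
      // ---- local scales: collapsed updates. Each lambda_j is slice-sampled
      // with beta_j integrated out analytically (the conditional marginal of
      // y given the other coefficients is Gaussian in beta_j), then beta_j is
      // redrawn from its conjugate conditional. Integrating beta_j out lets a
      // local scale jump between the shrunk and active regimes directly,
      // which the centered update cannot do when beta_j is currently small.
      resid = y - b0 - fitted;
      const double t2cur = std::exp(2.0 * log_tau);
      for (int j = 0; j < D; ++j) {
        const double bj_old = beta[j];
        const double sj = xtx_diag[j];
        // residual with marker j's contribution removed: r_j = resid + x_j b_j
        const double xr = arma::dot(X.col(j), resid) + sj * bj_old;
        const double q = xr / sigma2;          // x_j' r_j / sigma^2
        const double s_s2 = sj / sigma2;
        auto logf = [&](double u) {
          const double vv = prior_var(u, t2cur, c2);
          const double a = s_s2 + 1.0 / vv;
          return u - log1p_e2u(u) - 0.5 * std::log(vv * a) + 0.5 * q * q / a;
        };
        log_lambda[j] = slice1(log_lambda[j], logf, 1.5);
        const double vv = prior_var(log_lambda[j], t2cur, c2);
        const double a = s_s2 + 1.0 / vv;
        const double bj_new = q / a + norm_rand() / std::sqrt(a);
        beta[j] = bj_new;
        if (bj_new != bj_old) resid -= (bj_new - bj_old) * X.col(j);
      }
      fitted = y - b0 - resid;

      // ---- global scale: slice on log(tau), half-Cauchy(0, tau0)
      {
        auto logf = [&](double t) {
          double t2 = std::exp(2.0 * t);
          double s = 0.0;
          for (int j = 0; j < D; ++j) {
            double vv = prior_var(log_lambda[j], t2, c2);
            s += -0.5 * std::log(vv) - beta[j] * beta[j] / (2.0 * vv);
          }
          return t - std::log1p(std::exp(2.0 * (t - log_tau0))) + s;
        };
        log_tau = slice1(log_tau, logf, 2.0);
      }

      // ---- slab: slice on log(c^2), scaled-inv-chi-square prior
      if (sample_c2) {
        const double t2 = std::exp(2.0 * log_tau);
        auto logf = [&](double wv) {
          double cc = std::exp(wv);
          double s = -(slab_df / 2.0) * wv - slab_df * slab_s2 / (2.0 * cc);
          for (int j = 0; j < D; ++j) {
            double vv = prior_var(log_lambda[j], t2, cc);
            s += -0.5 * std::log(vv) - beta[j] * beta[j] / (2.0 * vv);
          }
          return s;
        };
        c2 = std::exp(slice1(std::log(c2), logf, 2.0));
      }

      // ---- interweaved (non-centered) update for tau: slice on log(tau)
      // with z = beta / prior SD held fixed, so the likelihood rather than
      // the conditional prior informs the move (ASIS); beta is rebuilt from
      // z at the accepted scale.
      {
        const double t2c = std::exp(2.0 * log_tau);
        arma::vec z(D);
        for (int j = 0; j < D; ++j)
          z[j] = beta[j] / std::sqrt(prior_var(log_lambda[j], t2c, c2));
        arma::vec bp(D);
        auto logf = [&](double lt) {
          const double t2 = std::exp(2.0 * lt);
          for (int j = 0; j < D; ++j)
            bp[j] = z[j] * std::sqrt(prior_var(log_lambda[j], t2, c2));
          arma::vec res = y - b0 - X * bp;
          return lt - std::log1p(std::exp(2.0 * (lt - log_tau0))) -
                 arma::dot(res, res) / (2.0 * sigma2);
        };
        log_tau = slice1(log_tau, logf, 1.0);
        const double t2n = std::exp(2.0 * log_tau);
        for (int j = 0; j < D; ++j)
          beta[j] = z[j] * std::sqrt(prior_var(log_lambda[j], t2n, c2));
        fitted = X * beta;
      }
      resid = y - b0 - fitted;

    }

    // ---- pairwise swap move between correlated markers
    resid = y - b0 - fitted;
    if (npairs > 0) {
      for (int s = 0; s < npairs; ++s) {
        int k = (int)(unif_rand() * npairs);
        if (k >= npairs) k = npairs - 1;
        const int i1 = swap_i[k], j1 = swap_j[k];
        const double d = beta[j1] - beta[i1];
        if (d == 0.0) continue;
        double uu = xtx_diag[i1] + xtx_diag[j1] - 2.0 * swap_g[k];
        double ur = arma::dot(X.col(i1), resid) - arma::dot(X.col(j1), resid);
        double ll = (2.0 * d * ur - d * d * uu) / (2.0 * sigma2);
        if (std::log(unif_rand()) < ll) {
          std::swap(beta[i1], beta[j1]);
          std::swap(log_lambda[i1], log_lambda[j1]);
          resid -= d * (X.col(i1) - X.col(j1));
        }
      }
    }
    fitted = y - b0 - resid;

    if (it >= warmup) {
      const int k = it - warmup;
      out_beta.row(k) = beta.t();
      out_scal(k, 0) = b0;
      out_scal(k, 1) = std::sqrt(sigma2);
      out_scal(k, 2) = std::exp(log_tau);
      out_scal(k, 3) = std::sqrt(c2);
    }
  }

  return List::create(_["beta"] = out_beta, _["scalars"] = out_scal);
}
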