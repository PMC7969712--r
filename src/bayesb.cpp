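#include <Rcpp.h>
using namespace Rcpp;

// BayesB Gibbs sampler with marginalized inclusion indicators.
//
// Model: y = 1*mu + sum_j x_j * beta_j + e, beta_j = delta_j * alpha_j,
//   P(delta_j = 0) = pi, alpha_j | delta_j = 1 ~ N(0, s2a_j),
//   s2a_j ~ nu * S / chisq_nu, sigma_e^2 ~ nu_e * Se / chisq_nu_e.
// X must be column-centered. Uses R's RNG: deterministic under set.seed().
//
// Per marker j the indicator is sampled with alpha_j integrated out:
//   log BF = 0.5 * [ log(se2) - log(c*s2a + se2) + rhs^2*s2a/(se2*(c*s2a+se2)) ]
// with c = x_j'x_j and rhs = x_j'r where r is the residual excluding j.

// [[Rcpp::export]]
List bayesb_mcmc(NumericMatrix X, NumericVector y, double pi_excl,
                 int n_iter, int burn_in, int thin,
                 double nu, double S, double nu_e, double Se,
                 bool update_sigma_alpha, double fixed_var) {
  const int n = X.nrow(), m = X.ncol();
  RNGScope scope;

  std::vector<double> xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    const double *xj = &X(0, j);
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xtx[j] = s;
  }

  // state
  double mu = Rcpp::mean(y);
  std::vector<double> beta(m, 0.0);        // delta_j * alpha_j
  std::vector<double> s2a(m, update_sigma_alpha ? nu * S / std::max(nu - 2.0, 0.5)
                                                : fixed_var);
  double se2 = 0.0;
  { double ss = 0.0; for (int i = 0; i < n; ++i) ss += (y[i]-mu)*(y[i]-mu);
    se2 = std::max(ss / n / 2.0, 1e-8); }
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  const double log_prior_odds = (pi_excl <= 0.0)
      ? R_PosInf : std::log(1.0 - pi_excl) - std::log(pi_excl);

  // accumulators over retained samples
  std::vector<double> beta_sum(m, 0.0), incl_sum(m, 0.0);
  double mu_sum = 0.0, se2_sum = 0.0;
  std::vector<double> mu_keep, se2_keep;
  int n_ret = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double r_mu = 0.0;
    for (int i = 0; i < n; ++i) r_mu += e[i] + mu;
    double mu_new = R::rnorm(r_mu / n, std::sqrt(se2 / n));
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    // markers
    for (int j = 0; j < m; ++j) {
      const double *xj = &X(0, j);
      const double c = xtx[j];
      if (c <= 0.0) { beta[j] = 0.0; continue; }
      // residual excluding marker j: r = e + x_j * beta_j
      double rhs = 0.0;
      const double bj_old = beta[j];
      for (int i = 0; i < n; ++i) rhs += xj[i] * (e[i] + xj[i] * bj_old);
      const double va = s2a[j];
      const double denom = c * va + se2;
      const double logBF = 0.5 * (std::log(se2) - std::log(denom)
                                  + rhs * rhs * va / (se2 * denom));
      bool include;
      if (!R_FINITE(log_prior_odds)) include = true;
      else {
        const double logit = log_prior_odds + logBF;
        const double p1 = 1.0 / (1.0 + std::exp(-logit));
        include = (R::unif_rand() < p1);
      }
      double bj_new = 0.0;
      if (include) {
        const double post_var = va * se2 / denom;
        const double post_mean = rhs * va / denom;
        bj_new = R::rnorm(post_mean, std::sqrt(post_var));
      }
      const double db = bj_new - bj_old;
      if (db != 0.0) for (int i = 0; i < n; ++i) e[i] -= xj[i] * db;
      beta[j] = bj_new;

      if (update_sigma_alpha) {
        if (include)
          s2a[j] = (nu * S + bj_new * bj_new) / R::rchisq(nu + 1.0);
        else
          s2a[j] = nu * S / R::rchisq(nu);
      }
      if (it >= burn_in && ((it - burn_in) % thin == 0))
        incl_sum[j] += include ? 1.0 : 0.0;
    }

    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    se2 = (sse + nu_e * Se) / R::rchisq((double)n + nu_e);
    if (!R_FINITE(se2) || se2 <= 0.0)
      stop("divergent residual variance at iteration %d", it + 1);

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      for (int j = 0; j < m; ++j) beta_sum[j] += beta[j];
      mu_sum += mu; se2_sum += se2;
      mu_keep.push_back(mu); se2_keep.push_back(se2);
      ++n_ret;
    }
  }

  NumericVector effect_mean(m), inclusion_prob(m);
  for (int j = 0; j < m; ++j) {
    effect_mean[j] = beta_sum[j] / n_ret;
    inclusion_prob[j] = incl_sum[j] / n_ret;
  }
  return List::create(_["effect_mean"] = effect_mean,
                      _["inclusion_prob"] = inclusion_prob,
                      _["mu_mean"] = mu_sum / n_ret,
                      _["sigma_e2_mean"] = se2_sum / n_ret,
                      _["mu_samples"] = NumericVector(mu_keep.begin(), mu_keep.end()),
                      _["sigma_e2_samples"] = NumericVector(se2_keep.begin(), se2_keep.end()),
                      _["n_retained"] = n_ret);
}
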