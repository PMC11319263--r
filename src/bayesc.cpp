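#include <Rcpp.h>
using namespace Rcpp;

// Spike-and-slab Gibbs sampler for whole-genome regression:
//   y = mu + sum_k z_k a_k delta_k + e
// with P(delta_k = 1) = 1 - pi, a_k | delta_k = 1 ~ N(0, s2a) sharing one
// common variance, scaled-inverse-chi^2 priors on s2a and s2e, flat prior
// on mu. Joint (delta_k, a_k) updates; uses R's RNG so set.seed() governs
// reproducibility.
//
// When fix_var is true, s2a and s2e are held at their starting values
// (degenerate priors), which with pi = 0 makes the posterior mean of the
// effects a ridge estimator.

static double rinvchisq(double df, double scale) {
  // scaled-inverse-chi^2(df, scale): df * scale / chi2_df
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export(name = ".bayesc_gibbs")]]
List bayesc_gibbs(NumericMatrix X, NumericVector y, double pi_zero,
                  int n_iter, int burn_in, int thin,
                  double nu_a, double S_a, double nu_e, double S_e,
                  double s2a_init, double s2e_init, bool fix_var,
                  bool keep_samples) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> xtx(p);
  {
    const double* xbase = X.begin();
    for (int j = 0; j < p; ++j) {
      const double* xj = xbase + (size_t)j * n;
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
      xtx[j] = s;
    }
  }

  std::vector<double> a(p, 0.0);      // current effects (0 when excluded)
  std::vector<int> delta(p, 0);
  double mu = Rcpp::mean(y);
  double s2a = s2a_init, s2e = s2e_init;
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  std::vector<double> a_post(p, 0.0);  // running mean of a_k * delta_k
  double mu_post = 0.0, s2a_post = 0.0, s2e_post = 0.0;
  double s2e_post2 = 0.0;
  int n_kept = 0;
  std::vector<double> s2e_samples;
  std::vector<double> incl_post(p, 0.0);

  const double log_prior_odds =
      std::log(std::max(1.0 - pi_zero, 1e-300)) -
      std::log(std::max(pi_zero, 1e-300));

  for (int it = 0; it < n_iter; ++it) {
    // mu | rest (flat prior)
    double esum = 0.0;
    for (int i = 0; i < n; ++i) esum += e[i] + mu;
    double mu_new = R::rnorm(esum / n, std::sqrt(s2e / n));
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    // (delta_k, a_k) jointly, common slab variance
    int m_in = 0;
    double ssa = 0.0;
    const double* xbase = X.begin();
    for (int j = 0; j < p; ++j) {
      const double* xj = xbase + (size_t)j * n;
      double rj = 0.0;  // z_j' e_{-j}
      const double aj_old = a[j];
      if (delta[j] == 1 && aj_old != 0.0) {
        for (int i = 0; i < n; ++i) rj += xj[i] * (e[i] + xj[i] * aj_old);
      } else {
        for (int i = 0; i < n; ++i) rj += xj[i] * e[i];
      }
      const double lambda = s2e / s2a;
      const double L = xtx[j] + lambda;
      // log Bayes factor for inclusion
      const double log_bf = 0.5 * std::log(lambda / L) +
        rj * rj / (2.0 * s2e * L);
      const double log_odds = log_prior_odds + log_bf;
      const double p_in = 1.0 / (1.0 + std::exp(-log_odds));
      const int dj = (R::unif_rand() < p_in) ? 1 : 0;
      double aj_new = 0.0;
      if (dj == 1) {
        aj_new = R::rnorm(rj / L, std::sqrt(s2e / L));
        ++m_in;
        ssa += aj_new * aj_new;
      }
      const double contrib_old = (delta[j] == 1) ? aj_old : 0.0;
      if (contrib_old != aj_new) {
        const double d = aj_new - contrib_old;
        for (int i = 0; i < n; ++i) e[i] -= xj[i] * d;
      }
      delta[j] = dj;
      a[j] = aj_new;
    }

    if (!fix_var) {
      s2a = rinvchisq(nu_a + m_in, (nu_a * S_a + ssa) / (nu_a + m_in));
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      s2e = rinvchisq(nu_e + n, (nu_e * S_e + sse) / (nu_e + n));
    }

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      ++n_kept;
      for (int j = 0; j < p; ++j) {
        if (delta[j] == 1) a_post[j] += a[j];
        incl_post[j] += delta[j];
      }
      mu_post += mu;
      s2a_post += s2a;
      s2e_post += s2e;
      s2e_post2 += s2e * s2e;
      if (keep_samples) s2e_samples.push_back(s2e);
    }
  }

  if (n_kept == 0) stop("no posterior samples kept (check chain settings)");
  NumericVector eff(p), incl(p);
  for (int j = 0; j < p; ++j) {
    eff[j] = a_post[j] / n_kept;
    incl[j] = incl_post[j] / n_kept;
  }
  double s2e_mean = s2e_post / n_kept;
  double s2e_var = s2e_post2 / n_kept - s2e_mean * s2e_mean;
  List out = List::create(
      _["mu"] = mu_post / n_kept, _["effects"] = eff,
      _["inclusion"] = incl, _["s2a"] = s2a_post / n_kept,
      _["s2e"] = s2e_mean, _["s2e_sd"] = std::sqrt(std::max(s2e_var, 0.0)),
      _["n_kept"] = n_kept);
  if (keep_samples) out["s2e_samples"] = NumericVector(s2e_samples.begin(),
                                                       s2e_samples.end());
  return out;
}
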