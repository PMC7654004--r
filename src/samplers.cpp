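// Gibbs sampler cores for the whole-genome regressions.
//
// State y = mu + Z a + e with standardized marker columns Z. BRR places one
// shared Gaussian prior N(0, sigma_a^2) on every effect; Bayes C-pi mixes a
// point mass at zero (probability pi) with the same Gaussian. Scaled
// inverse chi-square hyperpriors on both variances; flat prior on mu;
// Uniform(0,1) on pi when it is sampled. Effects are updated singly in
// fixed index order with running-residual bookkeeping. Uses R's RNG so
// set.seed() makes chains bit-reproducible.

#include <Rcpp.h>
using namespace Rcpp;

static inline double rinvchisq(double df, double scale_ss) {
  // scaled inverse chi-square draw: (SS + v*S2) / chisq_{df}
  return scale_ss / R::rchisq(df);
}

// [[Rcpp::export]]
List brr_gibbs_cpp(NumericVector y, NumericMatrix Z,
                   int n_iter, int burn_in, int thin,
                   double va, double S2a, double ve, double S2e,
                   double var_a0, double var_e0,
                   bool sample_var_a, bool sample_var_e) {
  const int n = y.size(), m = Z.ncol();
  std::vector<double> zsq(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    zsq[j] = s;
  }
  std::vector<double> a(m, 0.0), e(n);
  double mu = Rcpp::mean(y);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double var_a = var_a0, var_e = var_e0;

  const int n_ret = (n_iter - burn_in) / thin;
  NumericVector a_sum(m), a_sumsq(m);
  NumericVector var_a_draws(n_ret), var_e_draws(n_ret), mu_draws(n_ret);
  double mu_sum = 0.0;
  int ret = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // mu | rest (flat prior)
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar = ebar / n + mu;
    double mu_new = ebar + ::sqrt(var_e / n) * R::norm_rand();
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    // effects
    const double lambda = var_e / var_a;
    for (int j = 0; j < m; ++j) {
      double r = 0.0;
      for (int i = 0; i < n; ++i) r += Z(i, j) * e[i];
      r += zsq[j] * a[j];
      const double C = zsq[j] + lambda;
      const double a_new = r / C + ::sqrt(var_e / C) * R::norm_rand();
      const double diff = a_new - a[j];
      if (diff != 0.0)
        for (int i = 0; i < n; ++i) e[i] -= Z(i, j) * diff;
      a[j] = a_new;
    }

    if (sample_var_a) {
      double ss = 0.0;
      for (int j = 0; j < m; ++j) ss += a[j] * a[j];
      var_a = rinvchisq(va + m, ss + va * S2a);
    }
    if (sample_var_e) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) ss += e[i] * e[i];
      var_e = rinvchisq(ve + n, ss + ve * S2e);
    }
    if (!R_finite(mu) || !R_finite(var_a) || !R_finite(var_e))
      stop("brr_gibbs: non-finite state at iteration %d", it);

    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < m; ++j) {
        a_sum[j] += a[j];
        a_sumsq[j] += a[j] * a[j];
      }
      mu_sum += mu;
      mu_draws[ret] = mu;
      var_a_draws[ret] = var_a;
      var_e_draws[ret] = var_e;
      ++ret;
    }
  }
  return List::create(
    _["effect_means"] = a_sum / ret,
    _["effect_sds"] = Rcpp::sqrt(Rcpp::pmax(a_sumsq / ret -
                        Rcpp::pow(a_sum / ret, 2.0), 0.0)),
    _["mu_mean"] = mu_sum / ret,
    _["mu_draws"] = mu_draws,
    _["var_a_draws"] = var_a_draws,
    _["var_e_draws"] = var_e_draws,
    _["retained"] = ret);
}

// [[Rcpp::export]]
List cpi_gibbs_cpp(NumericVector y, NumericMatrix Z,
                   int n_iter, int burn_in, int thin,
                   double va, double S2a, double ve, double S2e,
                   double var_a0, double var_e0,
                   bool sample_var_a, bool sample_var_e,
                   double pi0, bool sample_pi) {
  const int n = y.size(), m = Z.ncol();
  std::vector<double> zsq(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    zsq[j] = s;
  }
  std::vector<double> a(m, 0.0);
  std::vector<int> delta(m, 1);
  std::vector<double> e(n);
  double mu = Rcpp::mean(y);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double var_a = var_a0, var_e = var_e0, pi = pi0;

  const int n_ret = (n_iter - burn_in) / thin;
  NumericVector a_sum(m), delta_sum(m);
  NumericVector pi_draws(n_ret), var_a_draws(n_ret), var_e_draws(n_ret);
  double mu_sum = 0.0;
  int ret = 0, empty_iters = 0;

  for (int it = 1; it <= n_iter; ++it) {
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar = ebar / n + mu;
    double mu_new = ebar + ::sqrt(var_e / n) * R::norm_rand();
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    int k_in = 0;
    for (int j = 0; j < m; ++j) {
      double r = 0.0;
      for (int i = 0; i < n; ++i) r += Z(i, j) * e[i];
      r += zsq[j] * a[j];
      const double C = zsq[j] + var_e / var_a;
      // log marginal-likelihood ratio of inclusion vs exclusion
      const double logBF = 0.5 * (::log(var_e) - ::log(var_a) - ::log(C)) +
        0.5 * r * r / (var_e * C);
      double p1;
      if (pi <= 0.0) p1 = 1.0;
      else if (pi >= 1.0) p1 = 0.0;
      else {
        const double lo = ::log(pi / (1.0 - pi)) - logBF;
        p1 = 1.0 / (1.0 + ::exp(lo));
      }
      const double a_old = a[j];
      if (R::unif_rand() < p1) {
        delta[j] = 1;
        a[j] = r / C + ::sqrt(var_e / C) * R::norm_rand();
        ++k_in;
      } else {
        delta[j] = 0;
        a[j] = 0.0;
      }
      const double diff = a[j] - a_old;
      if (diff != 0.0)
        for (int i = 0; i < n; ++i) e[i] -= Z(i, j) * diff;
    }

    if (sample_pi)
      pi = R::rbeta((double)(m - k_in) + 1.0, (double)k_in + 1.0);
    if (k_in == 0) ++empty_iters;

    if (sample_var_a) {
      if (k_in > 0) {
        double ss = 0.0;
        for (int j = 0; j < m; ++j) ss += a[j] * a[j];
        var_a = rinvchisq(va + k_in, ss + va * S2a);
      } else {
        var_a = rinvchisq(va, va * S2a);  // falls back to the prior
      }
    }
    if (sample_var_e) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) ss += e[i] * e[i];
      var_e = rinvchisq(ve + n, ss + ve * S2e);
    }
    if (!R_finite(mu) || !R_finite(var_a) || !R_finite(var_e) ||
        !R_finite(pi))
      stop("cpi_gibbs: non-finite state at iteration %d", it);

    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < m; ++j) {
        a_sum[j] += a[j];
        delta_sum[j] += delta[j];
      }
      mu_sum += mu;
      pi_draws[ret] = pi;
      var_a_draws[ret] = var_a;
      var_e_draws[ret] = var_e;
      ++ret;
    }
  }
  return List::create(
    _["effect_means"] = a_sum / ret,
    _["inclusion_probs"] = delta_sum / ret,
    _["mu_mean"] = mu_sum / ret,
    _["pi_draws"] = pi_draws,
    _["var_a_draws"] = var_a_draws,
    _["var_e_draws"] = var_e_draws,
    _["retained"] = ret,
    _["empty_model_iters"] = empty_iters);
}
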