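#include <Rcpp.h>
using namespace Rcpp;

// BayesCpi Gibbs sampler.
//
// Model: y = 1 mu + sum_k Z_k beta_k delta_k + e,
//        beta_k | delta_k = 1 ~ N(0, s2b) (common effect variance),
//        delta_k ~ Bernoulli(1 - pi), pi ~ Uniform(0, 1),
//        s2b, s2e ~ scaled-inv-chi2(nu = 4) with scales set from var(y)
//        at an assumed initial genomic h2 of 0.5.
//
// Z must be column-centered. Uses R's RNG, so set.seed() on the R side
// makes the chain exactly reproducible.

// [[Rcpp::export]]
List bayescpi_gibbs(NumericMatrix Z, NumericVector y, int n_iter,
                    int burn_in) {
  const int n = Z.nrow(), m = Z.ncol();
  const double nu = 4.0;

  // column sums of squares
  std::vector<double> zz(m);
  for (int k = 0; k < m; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, k) * Z(i, k);
    zz[k] = s;
  }

  double ybar = mean(y);
  double vy = var(y);
  if (vy <= 0) vy = 1e-8;
  double msx = 0.0;
  for (int k = 0; k < m; ++k) msx += zz[k] / n;
  if (msx <= 0) msx = 1e-8;

  const double S2e = vy * 0.5 * (nu - 2.0) / nu;
  // prior scale for the common effect variance is tied to the current
  // exclusion probability: the assumed genetic variance (half of var(y))
  // is spread over the markers currently expected to be included
  const double S2b_num = vy * 0.5 / msx * (nu - 2.0) / nu;

  double mu = ybar, s2e = vy * 0.5, pi = 0.5;
  double s2b = S2b_num / 0.5 * nu / (nu - 2.0);
  std::vector<double> a(m, 0.0);   // effective effect beta_k * delta_k
  std::vector<int> delta(m, 0);
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  // posterior accumulators
  std::vector<double> a_sum(m, 0.0), incl_sum(m, 0.0);
  double mu_sum = 0.0, pi_sum = 0.0, s2b_sum = 0.0, s2e_sum = 0.0;
  int n_keep = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = (mu + ebar) + R::rnorm(0.0, std::sqrt(s2e / n));
    double shift = mu - mu_new;
    for (int i = 0; i < n; ++i) e[i] += shift;
    mu = mu_new;

    // marker effects and inclusion indicators
    int m_in = 0;
    double ssb = 0.0;
    for (int k = 0; k < m; ++k) {
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += Z(i, k) * e[i];
      rhs += zz[k] * a[k];
      double C = zz[k] + s2e / s2b;
      double log_bf = 0.5 * std::log(s2e / (s2b * C)) +
                      0.5 * rhs * rhs / (s2e * C);
      double log_odds = std::log((1.0 - pi) / pi) + log_bf;
      double p_in = 1.0 / (1.0 + std::exp(-log_odds));
      double a_new = 0.0;
      int d_new = (R::unif_rand() < p_in) ? 1 : 0;
      if (d_new == 1) {
        a_new = R::rnorm(rhs / C, std::sqrt(s2e / C));
        ++m_in;
        ssb += a_new * a_new;
      }
      if (a_new != a[k]) {
        double diff = a[k] - a_new;
        for (int i = 0; i < n; ++i) e[i] += Z(i, k) * diff;
      }
      a[k] = a_new;
      delta[k] = d_new;
    }

    // variance components (scaled-inv-chi2 full conditionals); the s2b
    // prior scale adapts to the current expected number of included markers
    double frac_in = (1.0 - pi > 1.0 / m) ? (1.0 - pi) : (1.0 / m);
    double S2b = S2b_num / frac_in;
    s2b = (ssb + nu * S2b) / R::rchisq(nu + m_in);
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = (sse + nu * S2e) / R::rchisq(nu + n);

    // pi is the exclusion probability; uniform prior = Beta(1, 1)
    pi = R::rbeta(1.0 + (m - m_in), 1.0 + m_in);
    if (pi < 1e-8) pi = 1e-8;
    if (pi > 1.0 - 1e-8) pi = 1.0 - 1e-8;

    if (it >= burn_in) {
      ++n_keep;
      mu_sum += mu;
      pi_sum += pi;
      s2b_sum += s2b;
      s2e_sum += s2e;
      for (int k = 0; k < m; ++k) {
        a_sum[k] += a[k];
        incl_sum[k] += delta[k];
      }
    }
  }

  NumericVector beta_mean(m), incl_prob(m);
  for (int k = 0; k < m; ++k) {
    beta_mean[k] = a_sum[k] / n_keep;
    incl_prob[k] = incl_sum[k] / n_keep;
  }
  return List::create(_["beta_mean"] = beta_mean,
                      _["incl_prob"] = incl_prob,
                      _["mu_mean"] = mu_sum / n_keep,
                      _["pi_mean"] = pi_sum / n_keep,
                      _["s2beta_mean"] = s2b_sum / n_keep,
                      _["s2e_mean"] = s2e_sum / n_keep);
}
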