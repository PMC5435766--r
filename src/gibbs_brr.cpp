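#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for Bayesian ridge regression with one variance per
// effect class: y = mu + sum_j x_j beta_j + e, beta_j ~ N(0, s2[class_j]),
// scaled-inverse-chi-square priors on the class and residual variances.
// Per kept sample the realized variance (over individuals) of each class's
// genetic values is recorded. Uses R's RNG, so set.seed() on the R side
// makes chains reproducible.
//
// [[Rcpp::export]]
List gibbs_brr_cpp(NumericVector y, NumericMatrix X, IntegerVector cls,
                   int n_class, int n_iter, int burnin, int thin,
                   double df0, NumericVector S0, double dfe, double Se) {
  const int n = y.size();
  const int p = X.ncol();
  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  std::vector<int> pc(n_class, 0);
  for (int j = 0; j < p; ++j) pc[cls[j]]++;

  std::vector<double> beta(p, 0.0);
  std::vector<double> s2(n_class);
  for (int c = 0; c < n_class; ++c) s2[c] = S0[c];
  double s2e = Se;
  double mu = mean(y);
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  // per-class genetic values, maintained incrementally
  std::vector< std::vector<double> > g(n_class, std::vector<double>(n, 0.0));

  int n_keep = 0;
  for (int it = burnin; it < n_iter; ++it) if ((it - burnin) % thin == 0) ++n_keep;
  NumericMatrix var_samp(n_keep, n_class);
  NumericVector s2e_samp(n_keep);
  NumericMatrix s2_samp(n_keep, n_class);

  GetRNGstate();
  int keep = 0;
  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double esum = 0.0;
    for (int i = 0; i < n; ++i) esum += e[i];
    double mu_new = esum / n + mu + norm_rand() * std::sqrt(s2e / n);
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;
    // effects
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0.0) continue;
      const int c = cls[j];
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      rhs += xtx[j] * beta[j];
      const double cjj = xtx[j] + s2e / s2[c];
      const double bnew = rhs / cjj + norm_rand() * std::sqrt(s2e / cjj);
      const double db = bnew - beta[j];
      if (db != 0.0) {
        for (int i = 0; i < n; ++i) {
          const double d = db * X(i, j);
          e[i] -= d;
          g[c][i] += d;
        }
        beta[j] = bnew;
      }
    }
    // class variances
    for (int c = 0; c < n_class; ++c) {
      double ss = 0.0;
      for (int j = 0; j < p; ++j) if (cls[j] == c) ss += beta[j] * beta[j];
      s2[c] = (ss + df0 * S0[c]) / R::rchisq(df0 + pc[c]);
    }
    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = (sse + dfe * Se) / R::rchisq(dfe + n);

    if (it >= burnin && (it - burnin) % thin == 0) {
      for (int c = 0; c < n_class; ++c) {
        double m = 0.0, ss = 0.0;
        for (int i = 0; i < n; ++i) m += g[c][i];
        m /= n;
        for (int i = 0; i < n; ++i) ss += (g[c][i] - m) * (g[c][i] - m);
        var_samp(keep, c) = ss / n;
        s2_samp(keep, c) = s2[c];
      }
      s2e_samp[keep] = s2e;
      ++keep;
    }
  }
  PutRNGstate();
  return List::create(_["var_g"] = var_samp, _["s2_class"] = s2_samp,
                      _["s2e"] = s2e_samp);
}
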