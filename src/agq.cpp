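#include <Rcpp.h>
using namespace Rcpp;

// Marginal negative log-likelihood of a Poisson GLMM with one normal random
// intercept per group, integrated by adaptive Gauss-Hermite quadrature.
//
// The group-level integrand factorises, and because all observations of a
// group share one intercept c the conditional Poisson part collapses to
//   h(c) = S_y * c - E * exp(c) + A - c^2 / (2 s2) - log(sqrt(2 pi s2))
// with S_y = sum(y), E = sum(exp(eta)), A = sum(y * eta - lgamma(y + 1)),
// so the mode of h is found by a safeguarded scalar Newton iteration and the
// quadrature is centred and scaled there (adaptive GH). z and w are the
// physicists' Gauss-Hermite nodes/weights (weight function exp(-z^2)).
//
// [[Rcpp::export]]
double agq_poisson_nll(NumericVector beta, double log_sigma,
                       NumericVector y, NumericMatrix X, IntegerVector group,
                       int ngroups, NumericVector z, NumericVector w) {
  const int n = y.size(), p = beta.size(), K = z.size();
  const double sigma = std::exp(log_sigma), s2 = sigma * sigma;

  std::vector<double> Sy(ngroups, 0.0), E(ngroups, 0.0), A(ngroups, 0.0);
  for (int i = 0; i < n; ++i) {
    double eta = 0.0;
    for (int j = 0; j < p; ++j) eta += X(i, j) * beta[j];
    const int g = group[i];
    Sy[g] += y[i];
    E[g] += std::exp(eta);
    A[g] += y[i] * eta - R::lgammafn(y[i] + 1.0);
  }

  const double log_prior_const = -0.5 * std::log(2.0 * M_PI * s2);
  double nll = 0.0;
  for (int g = 0; g < ngroups; ++g) {
    // Newton for the conditional mode: h'(c) = Sy - E e^c - c/s2
    double c = 0.0;
    for (int it = 0; it < 100; ++it) {
      const double ec = E[g] * std::exp(c);
      const double g1 = Sy[g] - ec - c / s2;
      const double g2 = -ec - 1.0 / s2;  // strictly negative
      double step = g1 / g2;
      if (step > 5.0) step = 5.0; else if (step < -5.0) step = -5.0;
      c -= step;
      if (std::fabs(step) < 1e-12) break;
    }
    const double curv = E[g] * std::exp(c) + 1.0 / s2;
    const double s = 1.0 / std::sqrt(curv);

    // log sum over nodes of w_k exp(z_k^2) exp(h(c_k)), stabilised at the mode
    const double h0 = Sy[g] * c - E[g] * std::exp(c) + A[g] -
      c * c / (2.0 * s2) + log_prior_const;
    double acc = 0.0;
    for (int k = 0; k < K; ++k) {
      const double ck = c + M_SQRT2 * s * z[k];
      const double hk = Sy[g] * ck - E[g] * std::exp(ck) + A[g] -
        ck * ck / (2.0 * s2) + log_prior_const;
      acc += w[k] * std::exp(z[k] * z[k] + hk - h0);
    }
    nll -= h0 + std::log(acc) + std::log(M_SQRT2 * s);
  }
  return nll;
}

// Conditional modes of the chamber intercepts at given parameters (for
// diagnostics and for seeding the joint-mode Newton of other models).
// [[Rcpp::export]]
NumericVector agq_poisson_modes(NumericVector beta, double log_sigma,
                                NumericVector y, NumericMatrix X,
                                IntegerVector group, int ngroups) {
  const int n = y.size(), p = beta.size();
  const double sigma = std::exp(log_sigma), s2 = sigma * sigma;
  std::vector<double> Sy(ngroups, 0.0), E(ngroups, 0.0);
  for (int i = 0; i < n; ++i) {
    double eta = 0.0;
    for (int j = 0; j < p; ++j) eta += X(i, j) * beta[j];
    Sy[group[i]] += y[i];
    E[group[i]] += std::exp(eta);
  }
  NumericVector out(ngroups);
  for (int g = 0; g < ngroups; ++g) {
    double c = 0.0;
    for (int it = 0; it < 100; ++it) {
      const double ec = E[g] * std::exp(c);
      double step = (Sy[g] - ec - c / s2) / (-ec - 1.0 / s2);
      if (step > 5.0) step = 5.0; else if (step < -5.0) step = -5.0;
      c -= step;
      if (std::fabs(step) < 1e-12) break;
    }
    out[g] = c;
  }
  return out;
}
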