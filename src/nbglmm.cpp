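#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Negative marginal log-likelihood of a negative binomial (NB2) regression
// with a Gaussian random intercept per group, the intercept integrated out
// by adaptive Gauss-Hermite quadrature.
//
// Model: y_ij | b_i ~ NB2(mu_ij, alpha), log mu_ij = x_ij' beta + b_i,
//        b_i ~ N(0, sigma^2), Var(y|b) = mu + alpha mu^2.
//
// Per group the integrand's mode is found by damped Newton (the NB log-link
// log-likelihood is strictly concave in b), then the quadrature grid is
// centred and scaled at the mode: integral ~ sqrt(2) s_hat * sum_q w_q
// exp(x_q^2) exp(h(b_hat + sqrt(2) s_hat x_q)), accumulated in log space.
//
// gstart/gend are 0-based inclusive row ranges per group (rows sorted by
// group); gh_logw must be log(w_q) + x_q^2 for the physicists' GH rule.

// [[Rcpp::export]]
double nbglmm_nll_cpp(const NumericVector& y, const NumericMatrix& X,
                      const IntegerVector& gstart, const IntegerVector& gend,
                      const NumericVector& beta, double log_alpha,
                      double log_sigma, const NumericVector& gh_x,
                      const NumericVector& gh_logw) {
  const int n = y.size(), p = X.ncol(), G = gstart.size(), Q = gh_x.size();
  const double k = std::exp(-log_alpha);        // NB size = 1/alpha
  const double sigma = std::exp(log_sigma);
  const double sig2 = sigma * sigma;
  const double log_norm = std::log(sigma) + 0.5 * std::log(2.0 * M_PI);
  const double lgk = R::lgammafn(k);

  std::vector<double> eta(n), cst(n);
  for (int i = 0; i < n; i++) {
    double e = 0.0;
    for (int j = 0; j < p; j++) e += X(i, j) * beta[j];
    eta[i] = e;
    cst[i] = R::lgammafn(y[i] + k) - lgk - R::lgammafn(y[i] + 1.0) +
             k * std::log(k);
  }

  double nll = 0.0;
  for (int g = 0; g < G; g++) {
    const int a = gstart[g], b = gend[g];

    // h(b), optionally with first/second derivative in b
    auto hfun = [&](double bb, double* grad, double* hess) -> double {
      double h = 0.0, gr = 0.0, he = 0.0;
      for (int i = a; i <= b; i++) {
        const double mu = std::exp(eta[i] + bb);
        const double km = k + mu;
        h += cst[i] - (k + y[i]) * std::log(km) + y[i] * (eta[i] + bb);
        if (grad) {
          gr += y[i] - (y[i] + k) * mu / km;
          he -= (y[i] + k) * k * mu / (km * km);
        }
      }
      h -= bb * bb / (2.0 * sig2) + log_norm;
      if (grad) {
        *grad = gr - bb / sig2;
        *hess = he - 1.0 / sig2;
      }
      return h;
    };

    double bb = 0.0, gr, he;
    double h = hfun(bb, &gr, &he);
    for (int it = 0; it < 60; it++) {
      double step = -gr / he;
      if (!std::isfinite(step)) break;
      double bnew = bb + step;
      double g2, h2;
      double hn = hfun(bnew, &g2, &h2);
      int halv = 0;
      while ((!std::isfinite(hn) || hn < h - 1e-12) && halv < 40) {
        step *= 0.5;
        bnew = bb + step;
        hn = hfun(bnew, &g2, &h2);
        halv++;
      }
      const double moved = std::fabs(bnew - bb);
      bb = bnew; h = hn; gr = g2; he = h2;
      if (moved < 1e-10) break;
    }
    const double shat = 1.0 / std::sqrt(-he);

    double m = R_NegInf;
    std::vector<double> lt(Q);
    for (int q = 0; q < Q; q++) {
      const double bq = bb + M_SQRT2 * shat * gh_x[q];
      lt[q] = gh_logw[q] + hfun(bq, nullptr, nullptr);
      if (lt[q] > m) m = lt[q];
    }
    double s = 0.0;
    for (int q = 0; q < Q; q++) s += std::exp(lt[q] - m);
    nll -= m + std::log(s) + 0.5 * std::log(2.0) + std::log(shat);
  }
  return nll;
}
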