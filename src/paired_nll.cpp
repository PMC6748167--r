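#include <Rcpp.h>
using namespace Rcpp;

// Marginal negative log-likelihood of a beta GLMM with a logit mean link,
// a scalar precision phi, and one random intercept per grouping unit
// (sample), integrated out by adaptive Gauss-Hermite quadrature: the
// mode and curvature of each sample's integrand are located by a
// safeguarded Newton search and the nodes are centered/scaled there.
//
// par = [coef (p), log_phi, log_sigma]
// y, X: one row per observation (two per sample: 5-mC, 5-hmC)
// id: 0-based sample index per observation
// z, w: Gauss-Hermite nodes/weights for weight function exp(-z^2)
// sigma_zero: if true, ignore log_sigma and use the iid beta likelihood
// offset: optional per-observation linear-predictor offset (length n or 0)

// [[Rcpp::export]]
double paired_nll_cpp(NumericVector par, NumericVector y, NumericMatrix X,
                      IntegerVector id, int nsam, NumericVector z,
                      NumericVector w, bool sigma_zero,
                      NumericVector offset, NumericVector umode) {
  const int n = y.size(), p = X.ncol(), K = z.size();
  const bool warm = umode.size() == nsam;
  const bool has_off = offset.size() == n;
  std::vector<double> eta(n), ly(n), l1my(n), ystar(n);
  for (int i = 0; i < n; ++i) {
    double e = has_off ? offset[i] : 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * par[j];
    eta[i] = e;
    ly[i] = std::log(y[i]);
    l1my[i] = std::log1p(-y[i]);
    ystar[i] = ly[i] - l1my[i];
  }
  const double phi = std::exp(par[p]);
  if (!R_finite(phi) || phi <= 0.0) return 1e10;
  const double lgphi = R::lgammafn(phi);

  // log Beta(y_i | plogis(eta_i + u), phi) with precomputed constants
  auto ldens = [&](int i, double u) {
    double mu = 1.0 / (1.0 + std::exp(-(eta[i] + u)));
    double a = mu * phi, b = (1.0 - mu) * phi;
    return lgphi - R::lgammafn(a) - R::lgammafn(b) +
           (a - 1.0) * ly[i] + (b - 1.0) * l1my[i];
  };

  if (sigma_zero) {
    double ll = 0.0;
    for (int i = 0; i < n; ++i) ll += ldens(i, 0.0);
    return R_finite(ll) ? -ll : 1e10;
  }

  const double sigma = std::exp(par[p + 1]);
  if (!R_finite(sigma) || sigma <= 0.0) return 1e10;
  const double isig2 = 1.0 / (sigma * sigma);
  const double lognorm = -0.5 * std::log(2.0 * M_PI) - std::log(sigma);

  std::vector<std::vector<int>> obs(nsam);
  for (int i = 0; i < n; ++i) obs[id[i]].push_back(i);

  double ll = 0.0;
  for (int s = 0; s < nsam; ++s) {
    const std::vector<int> &ix = obs[s];
    if (ix.empty()) continue;

    auto h_val = [&](double u) {
      double v = lognorm - 0.5 * u * u * isig2;
      for (int j : ix) v += ldens(j, u);
      return v;
    };
    auto h_derivs = [&](double u, double &hp, double &hpp) {
      hp = -u * isig2;
      hpp = -isig2;
      for (int j : ix) {
        double mu = 1.0 / (1.0 + std::exp(-(eta[j] + u)));
        double wgt = mu * (1.0 - mu);
        double t = ystar[j] - R::digamma(mu * phi) +
                   R::digamma((1.0 - mu) * phi);
        hp += phi * t * wgt;
        hpp += phi * (-phi * wgt * wgt *
                        (R::trigamma(mu * phi) +
                         R::trigamma((1.0 - mu) * phi)) +
                      t * wgt * (1.0 - 2.0 * mu));
      }
    };

    // Newton for the mode: steps clamped to +-3; the integrand is
    // effectively concave near the mode, so damping is only engaged if
    // plain Newton fails to settle
    double u = warm ? umode[s] : 0.0, hp, hpp;
    bool done = false;
    for (int it = 0; it < 40; ++it) {
      h_derivs(u, hp, hpp);
      if (std::fabs(hp) < 1e-9) { done = true; break; }
      if (hpp > -1e-10) hpp = -1e-10;
      double step = -hp / hpp;
      if (step > 3.0) step = 3.0;
      if (step < -3.0) step = -3.0;
      u += step;
      if (std::fabs(step) < 1e-12) { done = true; break; }
    }
    if (!done) {  // damped fallback from the prior mode
      u = 0.0;
      double hval = h_val(0.0);
      for (int it = 0; it < 50; ++it) {
        h_derivs(u, hp, hpp);
        if (std::fabs(hp) < 1e-9) break;
        if (hpp > -1e-10) hpp = -1e-10;
        double step = -hp / hpp;
        if (step > 3.0) step = 3.0;
        if (step < -3.0) step = -3.0;
        double unew = u + step, hnew = h_val(unew);
        int halv = 0;
        while (hnew < hval && halv < 20) {
          step *= 0.5; unew = u + step; hnew = h_val(unew); ++halv;
        }
        if (hnew < hval || std::fabs(step) < 1e-12) break;
        u = unew; hval = hnew;
      }
      h_derivs(u, hp, hpp);
    }
    if (hpp > -1e-10) hpp = -1e-10;
    if (warm) umode[s] = u;
    const double sc = 1.0 / std::sqrt(-hpp);  // Laplace scale at the mode

    // adaptive GH:
    // integral = sqrt(2)*sc * sum_k w_k exp(z_k^2) f(u + sqrt2*sc*z_k)
    double m = R_NegInf;
    std::vector<double> terms(K);
    for (int k = 0; k < K; ++k) {
      double t = std::log(w[k]) + z[k] * z[k] +
                 h_val(u + M_SQRT2 * sc * z[k]);
      terms[k] = t;
      if (t > m) m = t;
    }
    if (!R_finite(m)) return 1e10;
    double acc = 0.0;
    for (int k = 0; k < K; ++k) acc += std::exp(terms[k] - m);
    ll += 0.5 * std::log(2.0) + std::log(sc) + m + std::log(acc);
  }
  return R_finite(ll) ? -ll : 1e10;
}

// Central-difference gradient of paired_nll_cpp in one call (avoids
// R-level finite-difference overhead during BFGS).
// [[Rcpp::export]]
NumericVector paired_nll_grad_cpp(NumericVector par, NumericVector y,
                                  NumericMatrix X, IntegerVector id,
                                  int nsam, NumericVector z,
                                  NumericVector w, bool sigma_zero,
                                  NumericVector offset, double h,
                                  NumericVector umode) {
  const int q = par.size();
  NumericVector g(q), pp = clone(par);
  for (int j = 0; j < q; ++j) {
    double orig = pp[j];
    pp[j] = orig + h;
    double fp = paired_nll_cpp(pp, y, X, id, nsam, z, w, sigma_zero,
                               offset, umode);
    pp[j] = orig - h;
    double fm = paired_nll_cpp(pp, y, X, id, nsam, z, w, sigma_zero,
                               offset, umode);
    pp[j] = orig;
    g[j] = (fp - fm) / (2.0 * h);
  }
  return g;
}
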