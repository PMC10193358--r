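// Numerical core for the mean-parameterised Conway-Maxwell-Poisson (MPCMP)
// distribution.  All series are finite (truncated at k terms) and evaluated
// in log space with the log-sum-exp trick; log r! via lgamma.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// log G(lambda, nu) = log sum_{r=0}^{k} exp(r*ll - nu*lgamma(r+1)),
// optionally with first two moments of the truncated distribution.
struct Moments {
  double logG;
  double mean;
  double var;
};

inline Moments cmp_moments_one(double ll, double nu, int k,
                               const double *lgf) {
  double m = -std::numeric_limits<double>::infinity();
  for (int r = 0; r <= k; ++r) {
    double t = r * ll - nu * lgf[r];
    if (t > m) m = t;
  }
  double s0 = 0.0, s1 = 0.0, s2 = 0.0;
  for (int r = 0; r <= k; ++r) {
    double w = std::exp(r * ll - nu * lgf[r] - m);
    s0 += w;
    s1 += r * w;
    s2 += double(r) * r * w;
  }
  Moments out;
  out.logG = m + std::log(s0);
  out.mean = s1 / s0;
  out.var = s2 / s0 - out.mean * out.mean;
  return out;
}

std::vector<double> lgf_table(int k) {
  std::vector<double> lgf(k + 1);
  for (int r = 0; r <= k; ++r) lgf[r] = std::lgamma(r + 1.0);
  return lgf;
}

// Hybrid bisection/Newton solver for the mean constraint mean(ll) = mu.
// The truncated mean is strictly increasing in ll, so the root is unique.
// Returns NaN when the bracket cannot be established.
double solve_one(double mu, double nu, int k, double tol,
                 const double *lgf) {
  if (!(mu > 0.0) || !(nu >= 0.0) || mu >= double(k)) return NA_REAL;
  double ll = std::log(mu);  // exact at nu = 1
  Moments mo = cmp_moments_one(ll, nu, k, lgf);
  double f = mo.mean - mu;
  double lo, hi;
  const double step = M_LN2;
  if (f == 0.0) return ll;
  if (f > 0.0) {
    hi = ll;
    lo = ll - step;
    int it = 0;
    while (cmp_moments_one(lo, nu, k, lgf).mean > mu) {
      hi = lo;
      lo -= step;
      if (++it > 200) return NA_REAL;
    }
  } else {
    lo = ll;
    hi = ll + step;
    int it = 0;
    while (cmp_moments_one(hi, nu, k, lgf).mean < mu) {
      lo = hi;
      hi += step;
      if (++it > 200) return NA_REAL;
    }
  }
  double x = 0.5 * (lo + hi);
  for (int it = 0; it < 200; ++it) {
    mo = cmp_moments_one(x, nu, k, lgf);
    f = mo.mean - mu;
    if (f > 0.0) hi = x; else lo = x;
    if (std::fabs(f) < 1e-13 * mu || (hi - lo) < tol) return x;
    double xn = x - f / mo.var;  // Newton: d mean / d ll = variance
    if (!(xn > lo && xn < hi) || !std::isfinite(xn))
      xn = 0.5 * (lo + hi);  // fall back to bisection
    x = xn;
  }
  return x;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_cmp_logG")]]
NumericVector cpp_cmp_logG(NumericVector log_lambda, NumericVector nu,
                           int k) {
  int n = log_lambda.size();
  std::vector<double> lgf = lgf_table(k);
  NumericVector out(n);
  bool nu_scalar = (nu.size() == 1);
  for (int i = 0; i < n; ++i) {
    double nui = nu_scalar ? nu[0] : nu[i];
    out[i] = cmp_moments_one(log_lambda[i], nui, k, lgf.data()).logG;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_cmp_moments")]]
List cpp_cmp_moments(NumericVector log_lambda, NumericVector nu, int k) {
  int n = log_lambda.size();
  std::vector<double> lgf = lgf_table(k);
  NumericVector logG(n), mean(n), var(n);
  bool nu_scalar = (nu.size() == 1);
  for (int i = 0; i < n; ++i) {
    double nui = nu_scalar ? nu[0] : nu[i];
    Moments mo = cmp_moments_one(log_lambda[i], nui, k, lgf.data());
    logG[i] = mo.logG;
    mean[i] = mo.mean;
    var[i] = mo.var;
  }
  return List::create(_["log_G"] = logG, _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export(name = ".cpp_solve_bisection")]]
List cpp_solve_bisection(NumericVector mu, NumericVector nu, int k,
                         double tol) {
  int n = mu.size();
  std::vector<double> lgf = lgf_table(k);
  NumericVector ll(n), logG(n);
  bool nu_scalar = (nu.size() == 1);
  for (int i = 0; i < n; ++i) {
    double nui = nu_scalar ? nu[0] : nu[i];
    double x = solve_one(mu[i], nui, k, tol, lgf.data());
    ll[i] = x;
    logG[i] = std::isnan(x)
                  ? NA_REAL
                  : cmp_moments_one(x, nui, k, lgf.data()).logG;
  }
  return List::create(_["log_lambda"] = ll, _["log_G"] = logG);
}

// Build the (mu, nu) -> log lambda grid; rows index mu nodes, columns nu
// nodes.  Nodes are independent, so any parallel split gives identical
// results.
// [[Rcpp::export(name = ".cpp_build_table")]]
NumericMatrix cpp_build_table(NumericVector mu_nodes, NumericVector nu_nodes,
                              int k, double tol) {
  int nm = mu_nodes.size(), nn = nu_nodes.size();
  std::vector<double> lgf = lgf_table(k);
  NumericMatrix out(nm, nn);
  for (int j = 0; j < nn; ++j) {
    for (int i = 0; i < nm; ++i) {
      double x = solve_one(mu_nodes[i], nu_nodes[j], k, tol, lgf.data());
      if (std::isnan(x))
        stop("look-up table build failed at mu = %f, nu = %f", mu_nodes[i],
             nu_nodes[j]);
      out(i, j) = x;
    }
  }
  return out;
}

// Bilinear interpolation/extrapolation on the table.  The mu weight is
// computed on the log-mu scale; the nu weight on the linear nu scale.
// Queries outside the hull reuse the nearest boundary cell with weights
// outside [0, 1].  Returns the values plus the number of extrapolated
// queries.
// [[Rcpp::export(name = ".cpp_lookup_loglambda")]]
List cpp_lookup_loglambda(NumericMatrix values, NumericVector mu_nodes,
                          NumericVector nu_nodes, bool log_spaced_mu,
                          NumericVector mu, NumericVector nu) {
  int nm = mu_nodes.size(), nn = nu_nodes.size(), n = mu.size();
  double mu_min = mu_nodes[0], mu_max = mu_nodes[nm - 1];
  double nu_min = nu_nodes[0], nu_max = nu_nodes[nn - 1];
  // uniform spacing on the node scale (mu or log mu)
  double a0 = log_spaced_mu ? std::log(mu_min) : mu_min;
  double a1 = log_spaced_mu ? std::log(mu_max) : mu_max;
  double astep = (a1 - a0) / (nm - 1);
  double nstep = (nu_max - nu_min) / (nn - 1);
  NumericVector out(n);
  int n_extra = 0;
  bool nu_scalar = (nu.size() == 1);
  for (int q = 0; q < n; ++q) {
    double mq = mu[q];
    double nq = nu_scalar ? nu[0] : nu[q];
    bool outside = (mq < mu_min || mq > mu_max || nq < nu_min || nq > nu_max);
    if (outside) ++n_extra;
    double pos = ((log_spaced_mu ? std::log(mq) : mq) - a0) / astep;
    // snap to a node when within fp noise so node queries are exact
    double rpos = std::round(pos);
    if (std::fabs(pos - rpos) < 1e-9) pos = rpos;
    int i = (int)std::floor(pos);
    if (i < 0) i = 0;
    if (i > nm - 2) i = nm - 2;
    double m1 = mu_nodes[i], m2 = mu_nodes[i + 1];
    double dmu = (std::log(mq) - std::log(m1)) / (std::log(m2) - std::log(m1));
    if (pos == rpos && rpos >= 0 && rpos <= nm - 1)
      dmu = (pos == double(i)) ? 0.0 : 1.0;
    double npos = (nq - nu_min) / nstep;
    double rnpos = std::round(npos);
    if (std::fabs(npos - rnpos) < 1e-9) npos = rnpos;
    int j = (int)std::floor(npos);
    if (j < 0) j = 0;
    if (j > nn - 2) j = nn - 2;
    double dnu = (nq - nu_nodes[j]) / (nu_nodes[j + 1] - nu_nodes[j]);
    if (npos == rnpos && rnpos >= 0 && rnpos <= nn - 1)
      dnu = (npos == double(j)) ? 0.0 : 1.0;
    out[q] = (1.0 - dmu) * (1.0 - dnu) * values(i, j) +
             dmu * (1.0 - dnu) * values(i + 1, j) +
             (1.0 - dmu) * dnu * values(i, j + 1) +
             dmu * dnu * values(i + 1, j + 1);
  }
  return List::create(_["log_lambda"] = out, _["n_extrapolated"] = n_extra);
}

// Single positive real root of sum_{r=0}^{k} (r - mu) lambda^r / (r!)^nu,
// via companion-matrix eigenvalues of the scaled coefficient vector.
// Coefficients are built in log space with explicit signs; trailing
// coefficients that underflow after scaling are dropped (their terms are
// negligible for any root of moderate size).
// [[Rcpp::export(name = ".cpp_solve_polynomial")]]
List cpp_solve_polynomial(NumericVector mu, NumericVector nu, int k) {
  int n = mu.size();
  std::vector<double> lgf = lgf_table(k);
  NumericVector ll(n);
  IntegerVector npos(n);
  bool nu_scalar = (nu.size() == 1);
  for (int q = 0; q < n; ++q) {
    double muq = mu[q];
    double nuq = nu_scalar ? nu[0] : nu[q];
    // log|c_r| and sign of c_r = (r - mu) / (r!)^nu
    std::vector<double> lc(k + 1);
    std::vector<int> sg(k + 1);
    double mx = -std::numeric_limits<double>::infinity();
    for (int r = 0; r <= k; ++r) {
      double d = r - muq;
      sg[r] = (d > 0) - (d < 0);
      lc[r] = (sg[r] == 0) ? -std::numeric_limits<double>::infinity()
                           : std::log(std::fabs(d)) - nuq * lgf[r];
      if (lc[r] > mx) mx = lc[r];
    }
    // Degree trimming: terms beyond the last one able to contribute more
    // than ~e^-36 of the dominant coefficient at any lambda up to a crude
    // closed-form root bound (3x the asymptotic rate (mu+(nu-1)/(2nu))^nu)
    // cannot move the positive root at the tolerances in play; companion
    // eigenvalue cost is cubic in the degree, so this matters.  A
    // mean-constraint residual check below falls back to the full degree.
    double base = std::max(muq / 2.0, muq + (nuq - 1.0) / (2.0 * std::max(nuq, 1e-8)));
    double log_ub = std::log(1.7 * std::max(std::max(std::pow(base, nuq), muq), 1.0));
    int min_deg = std::max((int)std::ceil(muq) + 2, 12);
    auto extract = [&](int kuse) -> std::pair<double, int> {
      int keff = kuse;
      while (keff > min_deg &&
             (sg[keff] == 0 || lc[keff] - mx < -700.0 ||
              (kuse == k && lc[keff] - mx + keff * log_ub < -30.0)))
        --keff;
      arma::vec coef(keff + 1);  // descending powers for arma::roots
      for (int r = 0; r <= keff; ++r)
        coef[keff - r] = (sg[r] == 0) ? 0.0 : sg[r] * std::exp(lc[r] - mx);
      arma::cx_vec rts;
      if (!arma::roots(rts, coef)) return {NA_REAL, 0};
      std::vector<double> pos_roots;
      for (arma::uword i = 0; i < rts.n_elem; ++i) {
        double re = rts[i].real(), im = rts[i].imag();
        if (std::fabs(im) < 1e-8 * (1.0 + std::fabs(re)) && re > 0.0)
          pos_roots.push_back(re);
      }
      if (pos_roots.empty()) return {NA_REAL, 0};
      if (pos_roots.size() == 1)
        return {std::log(pos_roots[0]), 1};
      // keep the root minimising the mean-constraint residual
      double best = NA_REAL, bestres = std::numeric_limits<double>::infinity();
      for (double r0 : pos_roots) {
        double res = std::fabs(
            cmp_moments_one(std::log(r0), nuq, k, lgf.data()).mean - muq);
        if (res < bestres) {
          bestres = res;
          best = std::log(r0);
        }
      }
      return {best, (int)pos_roots.size()};
    };
    std::pair<double, int> got = extract(k);
    if (std::isfinite(got.first)) {
      double res = std::fabs(
          cmp_moments_one(got.first, nuq, k, lgf.data()).mean - muq);
      if (res > 1e-6 * muq) {
        // trimmed degree was too aggressive for this (mu, nu): redo full
        int keff_full = k;
        while (keff_full > min_deg &&
               (sg[keff_full] == 0 || lc[keff_full] - mx < -700.0))
          --keff_full;
        arma::vec coef(keff_full + 1);
        for (int r = 0; r <= keff_full; ++r)
          coef[keff_full - r] = (sg[r] == 0) ? 0.0 : sg[r] * std::exp(lc[r] - mx);
        arma::cx_vec rts;
        if (arma::roots(rts, coef)) {
          std::vector<double> pos_roots;
          for (arma::uword i = 0; i < rts.n_elem; ++i) {
            double re = rts[i].real(), im = rts[i].imag();
            if (std::fabs(im) < 1e-8 * (1.0 + std::fabs(re)) && re > 0.0)
              pos_roots.push_back(re);
          }
          double best = got.first, bestres = res;
          for (double r0 : pos_roots) {
            double rr = std::fabs(
                cmp_moments_one(std::log(r0), nuq, k, lgf.data()).mean - muq);
            if (rr < bestres) { bestres = rr; best = std::log(r0); }
          }
          got.first = best;
          got.second = std::max(got.second, (int)pos_roots.size());
        }
      }
    }
    ll[q] = got.first;
    npos[q] = got.second;
  }
  return List::create(_["log_lambda"] = ll, _["n_positive_roots"] = npos);
}

// Per-observation MPCMP log-likelihood contributions given solved log
// lambda: y*ll - nu*lgamma(y+1) - logG(ll, nu).
// [[Rcpp::export(name = ".cpp_loglik_terms")]]
NumericVector cpp_loglik_terms(IntegerVector y, NumericVector log_lambda,
                               NumericVector nu, int k) {
  int n = y.size();
  std::vector<double> lgf = lgf_table(k);
  NumericVector out(n);
  bool nu_scalar = (nu.size() == 1);
  for (int i = 0; i < n; ++i) {
    double nui = nu_scalar ? nu[0] : nu[i];
    double ll = log_lambda[i];
    if (!std::isfinite(ll)) {
      out[i] = NA_REAL;
      continue;
    }
    Moments mo = cmp_moments_one(ll, nui, k, lgf.data());
    out[i] = y[i] * ll - nui * std::lgamma(y[i] + 1.0) - mo.logG;
  }
  return out;
}
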