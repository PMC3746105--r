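#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Univariate two-component Gaussian mixture fitted by EM, with the restart
// policy and variance floor shared by the direct fit, the parametric
// bootstrap and the subsampling comparison. Kept in C++ because the
// bootstrap refits the mixture on up to 100,000 simulated datasets.

struct MixFit {
  double w, mu1, mu2, v1, v2, ll;
  int iters;
  bool conv;
};

static inline double log_dnorm(double x, double mu, double v) {
  double d = x - mu;
  return -0.5 * (std::log(2.0 * M_PI * v) + d * d / v);
}

static double mix_loglik(const std::vector<double>& x, double w,
                         double mu1, double mu2, double v1, double v2) {
  double ll = 0.0;
  for (double xi : x) {
    double l1 = std::log(w) + log_dnorm(xi, mu1, v1);
    double l2 = std::log1p(-w) + log_dnorm(xi, mu2, v2);
    double m = std::max(l1, l2);
    ll += m + std::log(std::exp(l1 - m) + std::exp(l2 - m));
  }
  return ll;
}

static double normal_loglik(const std::vector<double>& x, double* mu_out,
                            double* v_out, double vfloor) {
  size_t n = x.size();
  double mu = 0.0;
  for (double xi : x) mu += xi;
  mu /= n;
  double v = 0.0;
  for (double xi : x) v += (xi - mu) * (xi - mu);
  v /= n;  // MLE divisor
  if (v < vfloor) v = vfloor;
  double ll = 0.0;
  for (double xi : x) ll += log_dnorm(xi, mu, v);
  if (mu_out) *mu_out = mu;
  if (v_out) *v_out = v;
  return ll;
}

// Project component variances onto the feasible set: both above the
// numerical floor and neither smaller than `vratio` times the other
// (Hathaway-style relative constraint, blocking single-point collapse).
static inline void project_vars(double& v1, double& v2, double vfloor,
                                double vratio) {
  if (v1 < vfloor) v1 = vfloor;
  if (v2 < vfloor) v2 = vfloor;
  if (v1 < vratio * v2) v1 = vratio * v2;
  else if (v2 < vratio * v1) v2 = vratio * v1;
}

static MixFit em_run(const std::vector<double>& x, double w, double mu1,
                     double mu2, double v1, double v2, double tol, int maxit,
                     double vfloor, double vratio) {
  size_t n = x.size();
  std::vector<double> r(n);
  project_vars(v1, v2, vfloor, vratio);
  double ll = mix_loglik(x, w, mu1, mu2, v1, v2);
  int it = 0;
  bool conv = false;
  for (it = 0; it < maxit; ++it) {
    // E step
    for (size_t i = 0; i < n; ++i) {
      double l1 = std::log(w) + log_dnorm(x[i], mu1, v1);
      double l2 = std::log1p(-w) + log_dnorm(x[i], mu2, v2);
      double m = std::max(l1, l2);
      double d = std::exp(l1 - m) + std::exp(l2 - m);
      r[i] = std::exp(l1 - m) / d;
    }
    // M step
    double s1 = 0.0, sx1 = 0.0, sx2 = 0.0;
    for (size_t i = 0; i < n; ++i) {
      s1 += r[i];
      sx1 += r[i] * x[i];
      sx2 += (1.0 - r[i]) * x[i];
    }
    double s2 = n - s1;
    if (s1 > 1e-12) mu1 = sx1 / s1;
    if (s2 > 1e-12) mu2 = sx2 / s2;
    double sv1 = 0.0, sv2 = 0.0;
    for (size_t i = 0; i < n; ++i) {
      sv1 += r[i] * (x[i] - mu1) * (x[i] - mu1);
      sv2 += (1.0 - r[i]) * (x[i] - mu2) * (x[i] - mu2);
    }
    // M-step for the variances under the relative constraint
    // v1 >= vratio*v2 and v2 >= vratio*v1: if the unconstrained optimum is
    // infeasible, the constrained optimum lies on the boundary v_small =
    // vratio * v_big, where the profile optimum is v_big = (A/vratio + B)/n
    // (A, B the responsibility-weighted sums of squares).
    v1 = (s1 > 1e-12) ? sv1 / s1 : vfloor;
    v2 = (s2 > 1e-12) ? sv2 / s2 : vfloor;
    if (v1 < vratio * v2) {
      double vb = (sv1 / vratio + sv2) / n;
      v2 = vb; v1 = vratio * vb;
    } else if (v2 < vratio * v1) {
      double vb = (sv2 / vratio + sv1) / n;
      v1 = vb; v2 = vratio * vb;
    }
    if (v1 < vfloor) v1 = vfloor;
    if (v2 < vfloor) v2 = vfloor;
    w = s1 / n;
    if (w < 1e-12) w = 1e-12;
    if (w > 1.0 - 1e-12) w = 1.0 - 1e-12;
    double ll_new = mix_loglik(x, w, mu1, mu2, v1, v2);
    if (std::fabs(ll_new - ll) < tol) {
      ll = ll_new;
      conv = true;
      ++it;
      break;
    }
    ll = ll_new;
  }
  MixFit f;
  f.w = w; f.mu1 = mu1; f.mu2 = mu2; f.v1 = v1; f.v2 = v2;
  f.ll = ll; f.iters = it; f.conv = conv;
  return f;
}

// Restart schedule: (1) degenerate start at the single-normal MLE (a fixed
// point of EM, guaranteeing mixture ll >= normal ll), (2) symmetric split of
// the single-normal solution, (3) lower/upper half quantile split, then
// random-assignment starts up to `restarts` total. Random starts draw from
// R's RNG so set.seed() governs them.
static MixFit em_best(const std::vector<double>& x, int restarts, double tol,
                      int maxit, double vfloor, double vratio, double mu_hat,
                      double v_hat) {
  size_t n = x.size();
  std::vector<double> xs(x);
  std::sort(xs.begin(), xs.end());
  double sd_hat = std::sqrt(v_hat);

  MixFit best = em_run(x, 0.5, mu_hat, mu_hat, v_hat, v_hat, tol, maxit, vfloor, vratio);
  int used = 1;

  if (restarts >= 2) {
    MixFit f = em_run(x, 0.5, mu_hat - 0.5 * sd_hat, mu_hat + 0.5 * sd_hat,
                      v_hat, v_hat, tol, maxit, vfloor, vratio);
    if (f.ll > best.ll) best = f;
    ++used;
  }
  if (restarts >= 3) {
    size_t h = n / 2;
    double m1 = 0.0, m2 = 0.0;
    for (size_t i = 0; i < h; ++i) m1 += xs[i];
    for (size_t i = h; i < n; ++i) m2 += xs[i];
    m1 /= h; m2 /= (n - h);
    double q1 = 0.0, q2 = 0.0;
    for (size_t i = 0; i < h; ++i) q1 += (xs[i] - m1) * (xs[i] - m1);
    for (size_t i = h; i < n; ++i) q2 += (xs[i] - m2) * (xs[i] - m2);
    q1 = std::max(q1 / h, vfloor);
    q2 = std::max(q2 / (n - h), vfloor);
    MixFit f = em_run(x, (double)h / n, m1, m2, q1, q2, tol, maxit, vfloor, vratio);
    if (f.ll > best.ll) best = f;
    ++used;
  }
  // Partition-based starts. Boundary optima of the constrained likelihood
  // correspond to tight contiguous blocks of the sorted sample, so for
  // small n every block-vs-complement partition is scored by its initial
  // log-likelihood (cheap, closed form) and EM is run from the best-ranked
  // ones; for larger n, tail splits at quantile-spaced cut points are used.
  int budget = restarts - used;
  if (budget > 0 && n <= 12) {
    struct Cand { double ll; double w, m1, m2, q1, q2; };
    std::vector<Cand> cands;
    for (size_t i = 0; i < n; ++i) {
      for (size_t j = i; j < n; ++j) {
        size_t len = j - i + 1;
        if (len >= n) continue;
        double m1 = 0.0, m2 = 0.0;
        for (size_t t = i; t <= j; ++t) m1 += xs[t];
        for (size_t t = 0; t < n; ++t) if (t < i || t > j) m2 += xs[t];
        m1 /= len; m2 /= (n - len);
        double q1 = 0.0, q2 = 0.0;
        for (size_t t = i; t <= j; ++t) q1 += (xs[t] - m1) * (xs[t] - m1);
        for (size_t t = 0; t < n; ++t)
          if (t < i || t > j) q2 += (xs[t] - m2) * (xs[t] - m2);
        q1 = std::max(q1 / len, vfloor);
        q2 = std::max(q2 / (double)(n - len), vfloor);
        project_vars(q1, q2, vfloor, vratio);
        Cand c;
        c.w = (double)len / n; c.m1 = m1; c.m2 = m2; c.q1 = q1; c.q2 = q2;
        c.ll = mix_loglik(x, c.w, m1, m2, q1, q2);
        cands.push_back(c);
      }
    }
    std::sort(cands.begin(), cands.end(),
              [](const Cand& a, const Cand& b) { return a.ll > b.ll; });
    for (size_t t = 0; t < cands.size() && used < restarts; ++t) {
      const Cand& c = cands[t];
      MixFit f = em_run(x, c.w, c.m1, c.m2, c.q1, c.q2, tol, maxit, vfloor, vratio);
      if (f.ll > best.ll) best = f;
      ++used;
    }
  } else if (budget > 0) {
    int n_splits = (int)n - 1;
    int keep_random = budget > 2 ? 2 : 0;
    int n_det = budget - keep_random;
    std::vector<int> ks;
    if (n_splits <= n_det) {
      for (int k = 1; k <= n_splits; ++k) ks.push_back(k);
    } else {
      for (int j = 0; j < n_det; ++j) {
        int k = 1 + (int)std::floor(j * (double)(n_splits - 1) /
                                    (n_det - 1 > 0 ? n_det - 1 : 1));
        if (ks.empty() || k != ks.back()) ks.push_back(k);
      }
    }
    for (size_t t = 0; t < ks.size() && used < restarts; ++t) {
      int k = ks[t];
      double m1 = 0.0, m2 = 0.0;
      for (int i = 0; i < k; ++i) m1 += xs[i];
      for (size_t i = k; i < n; ++i) m2 += xs[i];
      m1 /= k; m2 /= (n - k);
      double q1 = 0.0, q2 = 0.0;
      for (int i = 0; i < k; ++i) q1 += (xs[i] - m1) * (xs[i] - m1);
      for (size_t i = k; i < n; ++i) q2 += (xs[i] - m2) * (xs[i] - m2);
      q1 = std::max(q1 / k, vfloor);
      q2 = std::max(q2 / (double)(n - k), vfloor);
      MixFit f = em_run(x, (double)k / n, m1, m2, q1, q2, tol, maxit, vfloor, vratio);
      if (f.ll > best.ll) best = f;
      ++used;
    }
  }
  // random-assignment starts fill any remaining budget (R's RNG, so
  // set.seed() governs them); n <= 12 uses its full budget deterministically
  for (int rep = used; rep < restarts && n > 12; ++rep) {
    double s1 = 0.0, sx1 = 0.0, sx2 = 0.0;
    std::vector<int> z(n);
    int n1 = 0;
    for (size_t i = 0; i < n; ++i) {
      z[i] = (unif_rand() < 0.5) ? 1 : 0;
      n1 += z[i];
    }
    if (n1 == 0 || n1 == (int)n) { --rep; continue; }
    for (size_t i = 0; i < n; ++i) {
      if (z[i]) { s1 += 1.0; sx1 += x[i]; } else sx2 += x[i];
    }
    double m1 = sx1 / n1, m2 = sx2 / (n - n1);
    double q1 = 0.0, q2 = 0.0;
    for (size_t i = 0; i < n; ++i) {
      if (z[i]) q1 += (x[i] - m1) * (x[i] - m1);
      else q2 += (x[i] - m2) * (x[i] - m2);
    }
    q1 = std::max(q1 / n1, vfloor);
    q2 = std::max(q2 / (double)(n - n1), vfloor);
    MixFit f = em_run(x, (double)n1 / n, m1, m2, q1, q2, tol, maxit, vfloor, vratio);
    if (f.ll > best.ll) best = f;
    ++used;
  }
  best.iters = used;  // reuse field to report restarts actually run
  return best;
}

static double var_floor_for(const std::vector<double>& x, double rel) {
  size_t n = x.size();
  double mu = 0.0;
  for (double xi : x) mu += xi;
  mu /= n;
  double v = 0.0;
  for (double xi : x) v += (xi - mu) * (xi - mu);
  v /= n;
  double f = rel * v;
  if (f <= 0.0) f = 1e-12;
  return f;
}

// [[Rcpp::export]]
List cpp_fit_mixture2(NumericVector x, int restarts, double tol, int maxit,
                      double vfloor_rel, double vratio) {
  std::vector<double> xv(x.begin(), x.end());
  double vfloor = var_floor_for(xv, vfloor_rel);
  double mu_hat, v_hat;
  double ll0 = normal_loglik(xv, &mu_hat, &v_hat, vfloor);
  MixFit f = em_best(xv, restarts, tol, maxit, vfloor, vratio, mu_hat, v_hat);
  return List::create(
    _["weights"] = NumericVector::create(f.w, 1.0 - f.w),
    _["means"] = NumericVector::create(f.mu1, f.mu2),
    _["variances"] = NumericVector::create(f.v1, f.v2),
    _["loglik"] = f.ll,
    _["n_restarts_used"] = f.iters,
    _["converged"] = f.conv,
    _["normal_loglik"] = ll0,
    _["variance_floor"] = vfloor);
}

static double lambda_for(const std::vector<double>& x, int restarts,
                         double tol, int maxit, double vfloor_rel,
                         double vratio) {
  double vfloor = var_floor_for(x, vfloor_rel);
  double mu_hat, v_hat;
  double ll0 = normal_loglik(x, &mu_hat, &v_hat, vfloor);
  MixFit f = em_best(x, restarts, tol, maxit, vfloor, vratio, mu_hat, v_hat);
  double lam = 2.0 * (f.ll - ll0);
  return lam > 0.0 ? lam : 0.0;
}

// [[Rcpp::export]]
double cpp_lambda(NumericVector x, int restarts, double tol, int maxit,
                  double vfloor_rel, double vratio) {
  std::vector<double> xv(x.begin(), x.end());
  return lambda_for(xv, restarts, tol, maxit, vfloor_rel, vratio);
}

// Parametric bootstrap: B datasets of size n from N(mu, sigma2), each refit
// with the same configuration; returns the B test statistics.
// [[Rcpp::export]]
NumericVector cpp_bootstrap_lambdas(int n, double mu, double sigma2, int B,
                                    int restarts, double tol, int maxit,
                                    double vfloor_rel, double vratio) {
  NumericVector out(B);
  double sd = std::sqrt(sigma2);
  std::vector<double> x(n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) x[i] = mu + sd * norm_rand();
    out[b] = lambda_for(x, restarts, tol, maxit, vfloor_rel, vratio);
  }
  return out;
}

// m simple random subsamples of size k (without replacement within a draw),
// each reduced to its mixture-vs-normal statistic.
// [[Rcpp::export]]
NumericVector cpp_subsample_lambdas(NumericVector pool, int m, int k,
                                    int restarts, double tol, int maxit,
                                    double vfloor_rel, double vratio) {
  int n = pool.size();
  NumericVector out(m);
  std::vector<int> idx(n);
  std::vector<double> x(k);
  for (int s = 0; s < m; ++s) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = 0; i < k; ++i) {  // partial Fisher-Yates
      int j = i + (int)std::floor(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(idx[i], idx[j]);
      x[i] = pool[idx[i]];
    }
    out[s] = lambda_for(x, restarts, tol, maxit, vfloor_rel, vratio);
  }
  return out;
}
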