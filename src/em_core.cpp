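#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Two-component mixture over binary CpG methylation read vectors.
// A read enters the likelihood only through (M, l): p_{x,j} = m_j^M (1-m_j)^U.
// Methylation levels are clamped to [EPS_M, 1-EPS_M] inside the likelihood so
// reads impossible under m in {0,1} stay finite; the stored estimates are the
// raw M-step ratios.

static const double EPS_M = 1e-6;
static const double EPS_A = 1e-9;

static inline double clamp_m(double m) {
  if (m < EPS_M) return EPS_M;
  if (m > 1.0 - EPS_M) return 1.0 - EPS_M;
  return m;
}

struct Counts {
  std::vector<double> M, L, w;  // aggregated (M, l) classes with weights
};

// Aggregate identical (M, l) reads into weighted classes; reads within a bin
// are exchangeable given (M, l), so this changes nothing but speed.
static Counts aggregate(const NumericVector& M, const NumericVector& L,
                        const NumericVector& w) {
  Counts c;
  int n = M.size();
  for (int i = 0; i < n; ++i) {
    bool found = false;
    for (size_t k = 0; k < c.M.size(); ++k) {
      if (c.M[k] == M[i] && c.L[k] == L[i]) {
        c.w[k] += w[i];
        found = true;
        break;
      }
    }
    if (!found) {
      c.M.push_back(M[i]);
      c.L.push_back(L[i]);
      c.w.push_back(w[i]);
    }
  }
  return c;
}

struct EMResult {
  double m1, m2, a1, loglik;
  int n_iter;
  bool converged;
  std::vector<double> trace;
};

static EMResult em_fit(const Counts& c, double m1, double m2, double a1,
                       bool fix_alpha, double tol, int max_iter,
                       bool keep_trace) {
  int k = c.M.size();
  std::vector<double> q1(k);
  double W = 0.0;
  for (int i = 0; i < k; ++i) W += c.w[i];
  double ll_prev = R_NegInf, ll = R_NegInf;
  EMResult res;
  res.converged = false;
  int it;
  for (it = 1; it <= max_iter; ++it) {
    // E-step at current params; ll is the observed-data log-likelihood
    double c1 = clamp_m(m1), c2 = clamp_m(m2);
    double lm1 = std::log(c1), lu1 = std::log1p(-c1);
    double lm2 = std::log(c2), lu2 = std::log1p(-c2);
    double la1 = std::log(a1), la2 = std::log1p(-a1);
    ll = 0.0;
    for (int i = 0; i < k; ++i) {
      double U = c.L[i] - c.M[i];
      double lp1 = la1 + c.M[i] * lm1 + U * lu1;
      double lp2 = la2 + c.M[i] * lm2 + U * lu2;
      double mx = lp1 > lp2 ? lp1 : lp2;
      double lse = mx + std::log(std::exp(lp1 - mx) + std::exp(lp2 - mx));
      q1[i] = std::exp(lp1 - lse);
      ll += c.w[i] * lse;
    }
    if (keep_trace) res.trace.push_back(ll);
    if (!R_finite(ll)) break;
    if (std::fabs(ll - ll_prev) < tol) {
      // converged before updating: params and ll are consistent
      res.converged = true;
      break;
    }
    ll_prev = ll;
    // M-step: closed-form stationary point of the Jensen bound
    double s1 = 0, sm1 = 0, sl1 = 0, sm2 = 0, sl2 = 0;
    for (int i = 0; i < k; ++i) {
      double wq1 = c.w[i] * q1[i], wq2 = c.w[i] * (1.0 - q1[i]);
      s1 += wq1;
      sm1 += wq1 * c.M[i];
      sl1 += wq1 * c.L[i];
      sm2 += wq2 * c.M[i];
      sl2 += wq2 * c.L[i];
    }
    if (sl1 > 0) m1 = sm1 / sl1;
    if (sl2 > 0) m2 = sm2 / sl2;
    if (!fix_alpha) {
      a1 = s1 / W;
      if (a1 < EPS_A) a1 = EPS_A;
      if (a1 > 1.0 - EPS_A) a1 = 1.0 - EPS_A;
    }
  }
  res.m1 = m1;
  res.m2 = m2;
  res.a1 = a1;
  res.loglik = ll;
  res.n_iter = it > max_iter ? max_iter : it;
  return res;
}

// minor-component label convention: alpha1 <= 0.5
static void normalize_labels(EMResult& r) {
  if (r.a1 > 0.5) {
    std::swap(r.m1, r.m2);
    r.a1 = 1.0 - r.a1;
  }
}

// Free-alpha fit with the dual deterministic starts (0.2, 0.8) / (0.8, 0.2);
// the higher-likelihood convergence point is kept, ties resolved toward
// m1 <= m2.
static EMResult em_fit_free_dual(const Counts& c, double tol, int max_iter,
                                 bool keep_trace) {
  EMResult a = em_fit(c, 0.2, 0.8, 0.3, false, tol, max_iter, keep_trace);
  EMResult b = em_fit(c, 0.8, 0.2, 0.3, false, tol, max_iter, keep_trace);
  normalize_labels(a);
  normalize_labels(b);
  EMResult best;
  if (a.loglik > b.loglik) best = a;
  else if (b.loglik > a.loglik) best = b;
  else best = (a.m1 <= a.m2) ? a : b;
  return best;
}

static List result_to_list(const EMResult& r) {
  return List::create(_["m1"] = r.m1, _["m2"] = r.m2, _["alpha1"] = r.a1,
                      _["loglik"] = r.loglik, _["n_iter"] = r.n_iter,
                      _["converged"] = r.converged,
                      _["trace"] = NumericVector(r.trace.begin(),
                                                 r.trace.end()));
}

// [[Rcpp::export(rng = false)]]
List cpp_em_fit(NumericVector M, NumericVector L, double m1, double m2,
                double a1, bool fix_alpha, double tol, int max_iter,
                bool normalize) {
  NumericVector w(M.size(), 1.0);
  Counts c = aggregate(M, L, w);
  EMResult r = em_fit(c, m1, m2, a1, fix_alpha, tol, max_iter, true);
  if (normalize && !fix_alpha) normalize_labels(r);
  return result_to_list(r);
}

// [[Rcpp::export(rng = false)]]
List cpp_em_fit_free_dual(NumericVector M, NumericVector L, double tol,
                          int max_iter) {
  NumericVector w(M.size(), 1.0);
  Counts c = aggregate(M, L, w);
  EMResult r = em_fit_free_dual(c, tol, max_iter, true);
  return result_to_list(r);
}

// [[Rcpp::export(rng = false)]]
double cpp_loglik(NumericVector M, NumericVector L, double m1, double m2,
                  double a1) {
  double c1 = clamp_m(m1), c2 = clamp_m(m2);
  double lm1 = std::log(c1), lu1 = std::log1p(-c1);
  double lm2 = std::log(c2), lu2 = std::log1p(-c2);
  double la1 = std::log(a1), la2 = std::log1p(-a1);
  double ll = 0.0;
  for (int i = 0; i < M.size(); ++i) {
    double U = L[i] - M[i];
    double lp1 = la1 + M[i] * lm1 + U * lu1;
    double lp2 = la2 + M[i] * lm2 + U * lu2;
    double mx = lp1 > lp2 ? lp1 : lp2;
    ll += mx + std::log(std::exp(lp1 - mx) + std::exp(lp2 - mx));
  }
  return ll;
}

// Bootstrap a bin: n_boot resamples of |X| reads with replacement, each fit
// with the free-alpha dual-start EM; resamples with < 2 distinct (M, l)
// classes are redrawn up to max_retries times, else the bin is flagged.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_bootstrap_bin(NumericVector M, NumericVector L, int n_boot,
                       double tol, int max_iter, int max_retries) {
  int n = M.size();
  NumericMatrix out(n_boot, 4);
  colnames(out) = CharacterVector::create("m1", "m2", "alpha1", "loglik");
  bool failed = false;
  NumericVector Mb(n), Lb(n), w(n, 1.0);
  for (int b = 0; b < n_boot; ++b) {
    bool ok = false;
    Counts c;
    for (int attempt = 0; attempt <= max_retries && !ok; ++attempt) {
      for (int i = 0; i < n; ++i) {
        int j = (int)(unif_rand() * n);
        if (j == n) j = n - 1;
        Mb[i] = M[j];
        Lb[i] = L[j];
      }
      c = aggregate(Mb, Lb, w);
      ok = ((int)c.M.size() >= 2);
    }
    if (!ok) {
      failed = true;
      break;
    }
    EMResult r = em_fit_free_dual(c, tol, max_iter, false);
    out(b, 0) = r.m1;
    out(b, 1) = r.m2;
    out(b, 2) = r.a1;
    out(b, 3) = r.loglik;
  }
  return List::create(_["params"] = out, _["failed"] = failed);
}
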