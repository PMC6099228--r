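#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double nlogn(double v) { return v > 0.5 ? v * std::log(v) : 0.0; }

// Maximum-entropy integer allocation for given marginals: minimizes
// sum a*log(a) over the transportation polytope by successive shortest
// augmenting paths with convex unit costs (exact integer optimum; the
// continuous optimum is the expected-count table r_i c_j / m).
// [[Rcpp::export]]
NumericMatrix cpp_spread_max_alloc(NumericVector r, NumericVector c) {
  const int p = r.size(), q = c.size(), n = p + q;
  NumericMatrix a(p, q);
  std::vector<double> rd(r.begin(), r.end()), cd(c.begin(), c.end());
  double total = 0.0;
  for (int i = 0; i < p; ++i) total += rd[i];
  std::vector<double> dist(n);
  std::vector<int> prev(n);
  while (total > 0.5) {
    for (int k = 0; k < n; ++k) { dist[k] = R_PosInf; prev[k] = -1; }
    for (int i = 0; i < p; ++i) if (rd[i] > 0.5) dist[i] = 0.0;
    bool changed = true;
    for (int it = 0; it <= n && changed; ++it) {
      changed = false;
      for (int i = 0; i < p; ++i) {
        for (int j = 0; j < q; ++j) {
          const double aij = a(i, j);
          if (R_FINITE(dist[i])) {
            const double inc = nlogn(aij + 1.0) - nlogn(aij);
            if (dist[i] + inc < dist[p + j] - 1e-12) {
              dist[p + j] = dist[i] + inc; prev[p + j] = i; changed = true;
            }
          }
          if (aij > 0.5 && R_FINITE(dist[p + j])) {
            const double dec = nlogn(aij - 1.0) - nlogn(aij);
            if (dist[p + j] + dec < dist[i] - 1e-12) {
              dist[i] = dist[p + j] + dec; prev[i] = p + j; changed = true;
            }
          }
        }
      }
    }
    int t = -1; double best = R_PosInf;
    for (int j = 0; j < q; ++j)
      if (cd[j] > 0.5 && dist[p + j] < best) { best = dist[p + j]; t = j; }
    if (t < 0) stop("internal error: no augmenting path");
    int node = p + t;
    while (prev[node] >= 0) {
      const int pr = prev[node];
      if (node >= p) a(pr, node - p) += 1.0;   // forward row -> col
      else a(node, pr - p) -= 1.0;             // backward col -> row
      node = pr;
    }
    rd[node] -= 1.0; cd[t] -= 1.0; total -= 1.0;
  }
  return a;
}

static int arg_max(const std::vector<double>& v) {
  int k = 0;
  for (int i = 1; i < (int) v.size(); ++i) if (v[i] > v[k]) k = i;
  return k;  // ties -> lowest index
}

// classical greedy concentration: largest remaining row marginal paired
// with largest remaining column marginal; returns sum a*log(a)
static double plain_S(std::vector<double> r, std::vector<double> c,
                      double left) {
  double S = 0.0;
  while (left > 0.5) {
    const int i = arg_max(r), j = arg_max(c);
    const double v = std::min(r[i], c[j]);
    S += nlogn(v);
    r[i] -= v; c[j] -= v; left -= v;
  }
  return S;
}

// greedy variant preferring exact marginal matches (largest first): a row
// whose remaining total equals a column's can form a perfect block
static double match_S(std::vector<double> r, std::vector<double> c,
                      double left) {
  double S = 0.0;
  while (left > 0.5) {
    int bi = -1, bj = -1; double bv = -1.0;
    for (int i = 0; i < (int) r.size(); ++i) {
      if (r[i] < 0.5) continue;
      for (int j = 0; j < (int) c.size(); ++j) {
        if (c[j] < 0.5) continue;
        if (std::fabs(r[i] - c[j]) < 0.25 && r[i] > bv) { bv = r[i]; bi = i; bj = j; }
      }
    }
    if (bi < 0) { bi = arg_max(r); bj = arg_max(c); bv = std::min(r[bi], c[bj]); }
    S += nlogn(bv);
    r[bi] -= bv; c[bj] -= bv; left -= bv;
  }
  return S;
}

// one-step lookahead on the largest row: try every column, complete with
// the better of the two greedy rollouts
static double look_S(std::vector<double> r, std::vector<double> c,
                     double left) {
  double S = 0.0;
  while (left > 0.5) {
    const int i = arg_max(r);
    double bestS = -1.0; int bj = -1; double bv = 0.0;
    for (int j = 0; j < (int) c.size(); ++j) {
      if (c[j] < 0.5) continue;
      const double v = std::min(r[i], c[j]);
      std::vector<double> r2(r), c2(c);
      r2[i] -= v; c2[j] -= v;
      const double rest = std::max(plain_S(r2, c2, left - v),
                                   match_S(r2, c2, left - v));
      if (nlogn(v) + rest > bestS + 1e-12) { bestS = nlogn(v) + rest; bj = j; bv = v; }
    }
    S += nlogn(bv);
    r[i] -= bv; c[bj] -= bv; left -= bv;
  }
  return S;
}

// Concentration value sum a*log(a) of the most specialized integer
// allocation found by the greedy portfolio (all three variants yield
// realizable matrices, so the implied entropy is an inner bound).
// [[Rcpp::export]]
double cpp_conc_min_S(NumericVector r, NumericVector c) {
  std::vector<double> rv(r.begin(), r.end()), cv(c.begin(), c.end());
  double m = 0.0;
  for (double v : rv) m += v;
  double S = plain_S(rv, cv, m);
  S = std::max(S, match_S(rv, cv, m));
  S = std::max(S, look_S(rv, cv, m));
  return S;
}

// Integer-mode H2' of a count matrix in one call (hot path of the
// food-web resampling engine).
// [[Rcpp::export]]
double cpp_h2_prime_int(NumericMatrix a, double eps) {
  const int p = a.nrow(), q = a.ncol();
  std::vector<double> r, c(q, 0.0);
  double m = 0.0, Sobs = 0.0;
  for (int i = 0; i < p; ++i) {
    double ri = 0.0;
    for (int j = 0; j < q; ++j) {
      const double v = a(i, j);
      ri += v; c[j] += v; m += v; Sobs += nlogn(v);
    }
    if (ri > 0.5) r.push_back(ri);
  }
  std::vector<double> cc;
  for (int j = 0; j < q; ++j) if (c[j] > 0.5) cc.push_back(c[j]);
  if (m < 0.5) stop("web has no interactions (m = 0)");
  if (r.size() < 2 && cc.size() < 2) return 0.0;

  double Smin_alloc = plain_S(r, cc, m);
  Smin_alloc = std::max(Smin_alloc, match_S(r, cc, m));
  Smin_alloc = std::max(Smin_alloc, look_S(r, cc, m));
  const double hmin = std::log(m) - Smin_alloc / m;

  NumericVector rv(r.begin(), r.end()), cv(cc.begin(), cc.end());
  NumericMatrix amax = cpp_spread_max_alloc(rv, cv);
  double Smax_alloc = 0.0;
  for (int k = 0; k < amax.size(); ++k) Smax_alloc += nlogn(amax[k]);
  const double hmax = std::log(m) - Smax_alloc / m;

  const double span = hmax - hmin;
  if (span < eps) return 0.0;
  const double h2 = std::log(m) - Sobs / m;
  double h2p = (hmax - h2) / span;
  if (h2p < 0.0) h2p = 0.0;
  if (h2p > 1.0) h2p = 1.0;
  return h2p;
}
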