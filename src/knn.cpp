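#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// kth-nearest-neighbour Euclidean distances for every row of X.
// Brute force: with d up to ~36 a kd-tree degenerates to linear scan
// anyway, and n here is a few thousand.
// [[Rcpp::export(.knn_kth_dist)]]
NumericVector knn_kth_dist(NumericMatrix X, int k) {
  const int n = X.nrow(), d = X.ncol();
  if (k < 1 || k >= n) stop("need 1 <= k < n");
  NumericVector out(n);
  // column-major access: copy to row-major for cache locality
  std::vector<double> M((size_t)n * d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < n; ++i)
      M[(size_t)i * d + j] = X(i, j);
  std::vector<double> dist(n);
  for (int i = 0; i < n; ++i) {
    const double *xi = &M[(size_t)i * d];
    for (int j = 0; j < n; ++j) {
      const double *xj = &M[(size_t)j * d];
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double t = xi[c] - xj[c];
        s += t * t;
      }
      dist[j] = s;
    }
    dist[i] = R_PosInf;  // exclude self
    std::nth_element(dist.begin(), dist.begin() + (k - 1), dist.end());
    out[i] = std::sqrt(dist[k - 1]);
  }
  return out;
}

// Greedy sup-metric thinning: visit rows in the given order (1-based);
// retain a row iff its sup-distance to every already-retained row is >= d.
// [[Rcpp::export(.greedy_thin)]]
LogicalVector greedy_thin(NumericMatrix X, double d, IntegerVector order) {
  const int n = X.nrow(), p = X.ncol();
  if (order.size() != n) stop("order must permute all rows");
  LogicalVector keep(n, false);
  std::vector<double> M((size_t)n * p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i)
      M[(size_t)i * p + j] = X(i, j);
  std::vector<int> retained;
  retained.reserve(n);
  for (int oi = 0; oi < n; ++oi) {
    const int i = order[oi] - 1;
    const double *xi = &M[(size_t)i * p];
    bool ok = true;
    for (size_t r = 0; r < retained.size() && ok; ++r) {
      const double *xr = &M[(size_t)retained[r] * p];
      double m = 0.0;
      for (int c = 0; c < p; ++c) {
        const double t = std::fabs(xi[c] - xr[c]);
        if (t > m) m = t;
        if (m >= d) break;  // already far enough; keep scanning others
      }
      if (m < d) ok = false;
    }
    if (ok) {
      keep[i] = true;
      retained.push_back(i);
    }
  }
  return keep;
}

// Log mixture density (natural log) of heteroscedastic diagonal-Gaussian
// channel outputs: f(y) = mean_i prod_c Normal(y_c; q_ic, sd_ic).
// q, sd are n x c mixture parameters; y is m x c evaluation points.
// [[Rcpp::export(.mix_logdensity)]]
NumericVector mix_logdensity(NumericMatrix q, NumericMatrix sd,
                             NumericMatrix y) {
  const int n = q.nrow(), c = q.ncol(), m = y.nrow();
  if (sd.nrow() != n || sd.ncol() != c || y.ncol() != c)
    stop("dimension mismatch");
  const double log2pi_half = 0.5 * std::log(2.0 * M_PI);
  // precompute per-component log-sd sums and row-major copies
  std::vector<double> Q((size_t)n * c), S((size_t)n * c), lsd(n, 0.0);
  for (int j = 0; j < c; ++j)
    for (int i = 0; i < n; ++i) {
      Q[(size_t)i * c + j] = q(i, j);
      const double s = sd(i, j);
      if (s <= 0) stop("sd must be positive");
      S[(size_t)i * c + j] = s;
      lsd[i] += std::log(s);
    }
  NumericVector out(m);
  std::vector<double> ll(n);
  for (int t = 0; t < m; ++t) {
    double mx = R_NegInf;
    for (int i = 0; i < n; ++i) {
      const double *qi = &Q[(size_t)i * c];
      const double *si = &S[(size_t)i * c];
      double s = -lsd[i] - c * log2pi_half;
      for (int j = 0; j < c; ++j) {
        const double z = (y(t, j) - qi[j]) / si[j];
        s -= 0.5 * z * z;
      }
      ll[i] = s;
      if (s > mx) mx = s;
    }
    double acc = 0.0;
    for (int i = 0; i < n; ++i) acc += std::exp(ll[i] - mx);
    out[t] = mx + std::log(acc / n);
  }
  return out;
}
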