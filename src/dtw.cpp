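#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Dynamic-programming DTW cost with |s[i] - t[j]| cell costs and the three
// standard moves; w < 0 means unconstrained, otherwise only cells with
// |i - j| <= w are reachable (Sakoe-Chiba band). Two rolling rows keep memory
// at O(m).
static double dtw_core(const double* s, int n, const double* t, int m, int w) {
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), inf);
    int jlo = 1, jhi = m;
    if (w >= 0) {
      jlo = std::max(1, i - w);
      jhi = std::min(m, i + w);
      if (jlo > jhi) return inf;
    }
    for (int j = jlo; j <= jhi; ++j) {
      double cost = std::fabs(s[i - 1] - t[j - 1]);
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = cost + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector s, NumericVector t, int w) {
  return dtw_core(s.begin(), s.size(), t.begin(), t.size(), w);
}

// Pairwise DTW over the rows of a series matrix (all series equal length).
// [[Rcpp::export]]
NumericMatrix pairwise_dtw_cpp(NumericMatrix x, int w) {
  int n = x.nrow(), L = x.ncol();
  NumericMatrix out(n, n);
  std::vector<double> a(L), b(L);
  for (int i = 0; i < n; ++i) {
    for (int l = 0; l < L; ++l) a[l] = x(i, l);
    for (int j = i + 1; j < n; ++j) {
      for (int l = 0; l < L; ++l) b[l] = x(j, l);
      double d = dtw_core(a.data(), L, b.data(), L, w);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}

// DTW of the rows of x (n series) against the rows of y (m series).
// [[Rcpp::export]]
NumericMatrix cross_dtw_cpp(NumericMatrix x, NumericMatrix y, int w) {
  int n = x.nrow(), m = y.nrow(), L = x.ncol();
  NumericMatrix out(n, m);
  std::vector<double> a(L), b(L);
  for (int i = 0; i < n; ++i) {
    for (int l = 0; l < L; ++l) a[l] = x(i, l);
    for (int j = 0; j < m; ++j) {
      for (int l = 0; l < L; ++l) b[l] = y(j, l);
      out(i, j) = dtw_core(a.data(), L, b.data(), L, w);
    }
  }
  return out;
}
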