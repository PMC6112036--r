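#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Euclidean distance between row i of A and row j of B (same ncol).
static inline double euclid(const NumericMatrix& A, int i,
                            const NumericMatrix& B, int j) {
  double s = 0.0;
  for (int c = 0; c < A.ncol(); ++c) {
    double d = A(i, c) - B(j, c);
    s += d * d;
  }
  return std::sqrt(s);
}

// Full DTW between query (m x d) and reference (n x d).
// Steps {(1,0),(0,1),(1,1)}; boundary (0,0) .. (m-1,n-1).
// Backtracking tie-break: diagonal, then (i-1,j), then (i,j-1).
// Returns distance, path (1-based index pairs), path length.
// [[Rcpp::export(name = ".dtw_full_cpp")]]
List dtw_full_cpp(NumericMatrix query, NumericMatrix reference,
                  bool want_path = true) {
  const int m = query.nrow(), n = reference.nrow();
  NumericMatrix D(m, n);
  D(0, 0) = euclid(query, 0, reference, 0);
  for (int i = 1; i < m; ++i) D(i, 0) = D(i - 1, 0) + euclid(query, i, reference, 0);
  for (int j = 1; j < n; ++j) D(0, j) = D(0, j - 1) + euclid(query, 0, reference, j);
  for (int i = 1; i < m; ++i) {
    for (int j = 1; j < n; ++j) {
      double best = D(i - 1, j - 1);
      if (D(i - 1, j) < best) best = D(i - 1, j);
      if (D(i, j - 1) < best) best = D(i, j - 1);
      D(i, j) = euclid(query, i, reference, j) + best;
    }
  }
  if (!want_path) {
    return List::create(_["distance"] = D(m - 1, n - 1));
  }
  std::vector<int> pi, pj;
  int i = m - 1, j = n - 1;
  pi.push_back(i + 1); pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    if (i == 0) { --j; }
    else if (j == 0) { --i; }
    else {
      double diag = D(i - 1, j - 1), up = D(i - 1, j), left = D(i, j - 1);
      if (diag <= up && diag <= left) { --i; --j; }
      else if (up <= left) { --i; }
      else { --j; }
    }
    pi.push_back(i + 1); pj.push_back(j + 1);
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  IntegerMatrix path(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) { path(k, 0) = pi[k]; path(k, 1) = pj[k]; }
  return List::create(_["distance"] = D(m - 1, n - 1),
                      _["path"] = path,
                      _["path_length"] = (int)pi.size());
}

// Subsequence DTW: template (m x d) against series (n x d) with free start.
// Row 0 of the accumulated matrix is the local cost (no penalty for where
// the match begins). Alongside the costs, the start column and the warping
// path length of the optimal path are propagated cell-by-cell with the same
// tie-break as backtracking (diagonal, vertical, horizontal), so each end
// position j yields (cost, start, path length) in O(1).
// [[Rcpp::export(name = ".dtw_subseq_cpp")]]
List dtw_subseq_cpp(NumericMatrix tmpl, NumericMatrix series) {
  const int m = tmpl.nrow(), n = series.nrow();
  NumericMatrix D(m, n);
  IntegerMatrix S(m, n);  // 1-based start index of the optimal path
  IntegerMatrix L(m, n);  // number of cells on the optimal path
  for (int j = 0; j < n; ++j) {
    D(0, j) = euclid(tmpl, 0, series, j);
    S(0, j) = j + 1;
    L(0, j) = 1;
  }
  for (int i = 1; i < m; ++i) {
    // j = 0: only vertical predecessor exists
    D(i, 0) = D(i - 1, 0) + euclid(tmpl, i, series, 0);
    S(i, 0) = 1;
    L(i, 0) = L(i - 1, 0) + 1;
    for (int j = 1; j < n; ++j) {
      double diag = D(i - 1, j - 1), up = D(i - 1, j), left = D(i, j - 1);
      int pi_, pj_;
      if (diag <= up && diag <= left) { pi_ = i - 1; pj_ = j - 1; }
      else if (up <= left)            { pi_ = i - 1; pj_ = j; }
      else                            { pi_ = i;     pj_ = j - 1; }
      D(i, j) = euclid(tmpl, i, series, j) + D(pi_, pj_);
      S(i, j) = S(pi_, pj_);
      L(i, j) = L(pi_, pj_) + 1;
    }
  }
  NumericVector last_row(n);
  IntegerVector starts(n), plen(n);
  for (int j = 0; j < n; ++j) {
    last_row[j] = D(m - 1, j);
    starts[j] = S(m - 1, j);
    plen[j] = L(m - 1, j);
  }
  return List::create(_["last_row"] = last_row,
                      _["start_index"] = starts,
                      _["path_length"] = plen);
}
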