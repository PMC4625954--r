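#include <Rcpp.h>
using namespace Rcpp;

// Dynamic programming for the squared-difference DTW cost between two
// methylation signatures y1 (length m) and y2 (length n).
//
// boundary codes:
//   0 "partial": free start on the first row/column, free end on the last
//     row/column ({m} x [1,n] U [1,m] x {n}).
//   1 "fixed":   classical endpoints (1,1) -> (m,n).
//   2 "printed": free start as in "partial"; end set {n} x [1,n] U [1,m] x {n}
//     taken verbatim (the first component indexes y1, so it is only feasible
//     when n <= m). Asymmetric; symmetrise at the matrix level.
//
// Steps are (1,0), (0,1), (1,1): each index advances by 0 or 1, at least one
// advances. All admissible single cells count as length-1 paths.
// [[Rcpp::export(name = ".dtw_cost")]]
double dtw_cost(NumericVector y1, NumericVector y2, int boundary,
                bool normalize) {
  const int m = y1.size(), n = y2.size();
  if (m == 0 || n == 0) stop("empty signature");
  NumericMatrix C(m, n);
  IntegerMatrix L(m, n); // path length (number of cells) of the optimum at (i,j)
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      const double d = (y1[i] - y2[j]) * (y1[i] - y2[j]);
      double prev = R_PosInf;
      int plen = 0;
      if (i > 0 && C(i - 1, j) < prev) { prev = C(i - 1, j); plen = L(i - 1, j); }
      if (j > 0 && C(i, j - 1) < prev) { prev = C(i, j - 1); plen = L(i, j - 1); }
      if (i > 0 && j > 0 && C(i - 1, j - 1) < prev) {
        prev = C(i - 1, j - 1); plen = L(i - 1, j - 1);
      }
      const bool can_start =
          (boundary == 1) ? (i == 0 && j == 0) : (i == 0 || j == 0);
      if (can_start && prev >= 0.0) { prev = 0.0; plen = 0; }
      C(i, j) = d + prev;
      L(i, j) = plen + 1;
    }
  }
  double best = R_PosInf;
  int blen = 1;
  if (boundary == 1) {
    best = C(m - 1, n - 1);
    blen = L(m - 1, n - 1);
  } else if (boundary == 0) {
    for (int j = 0; j < n; ++j)
      if (C(m - 1, j) < best) { best = C(m - 1, j); blen = L(m - 1, j); }
    for (int i = 0; i < m; ++i)
      if (C(i, n - 1) < best) { best = C(i, n - 1); blen = L(i, n - 1); }
  } else {
    if (n - 1 < m)
      for (int j = 0; j < n; ++j)
        if (C(n - 1, j) < best) { best = C(n - 1, j); blen = L(n - 1, j); }
    for (int i = 0; i < m; ++i)
      if (C(i, n - 1) < best) { best = C(i, n - 1); blen = L(i, n - 1); }
  }
  if (normalize && R_finite(best)) best /= blen;
  return best;
}

// Pairwise DTW dissimilarity matrix over a list of numeric vectors.
// Symmetrised by averaging d(i,j) and d(j,i); for boundaries 0 and 1 the two
// directions coincide exactly, for 2 they generally do not.
// [[Rcpp::export(name = ".dtw_matrix")]]
NumericMatrix dtw_matrix(List ys, int boundary, bool normalize) {
  const int p = ys.size();
  NumericMatrix D(p, p);
  std::vector<NumericVector> v(p);
  for (int i = 0; i < p; ++i) v[i] = as<NumericVector>(ys[i]);
  for (int i = 0; i < p; ++i) {
    for (int j = i + 1; j < p; ++j) {
      double dij = dtw_cost(v[i], v[j], boundary, normalize);
      if (boundary == 2) {
        const double dji = dtw_cost(v[j], v[i], boundary, normalize);
        dij = 0.5 * (dij + dji);
      }
      D(i, j) = dij;
      D(j, i) = dij;
    }
  }
  return D;
}
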