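#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh) over a precomputed position-pair
// score matrix S (rows: profile A columns, cols: profile B columns).
// Opening a gap costs gap_open for its first position and gap_extend
// for each further position. Returns the best score, the number of
// aligned (diagonal) column pairs on the optimal path, and the aligned
// ranges (1-based, inclusive).
// [[Rcpp::export]]
List align_matrix_local(NumericMatrix S, double gap_open, double gap_extend) {
  int n = S.nrow(), m = S.ncol();
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  IntegerMatrix tb(n + 1, m + 1); // 0 stop, 1 diag, 2 up (gap in B), 3 left (gap in A)
  double best = 0.0; int bi = 0, bj = 0;
  const double NEG = -1e30;
  for (int i = 0; i <= n; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }
  for (int j = 0; j <= m; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E(i, j) = std::max(H(i, j - 1) - gap_open, E(i, j - 1) - gap_extend);
      F(i, j) = std::max(H(i - 1, j) - gap_open, F(i - 1, j) - gap_extend);
      double diag = H(i - 1, j - 1) + S(i - 1, j - 1);
      double h = 0.0; int t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (F(i, j) > h) { h = F(i, j); t = 2; }
      if (E(i, j) > h) { h = E(i, j); t = 3; }
      H(i, j) = h; tb(i, j) = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback counting diagonal steps
  int aligned = 0, i = bi, j = bj;
  int ai_end = bi, aj_end = bj;
  while (i > 0 && j > 0 && H(i, j) > 0) {
    int t = tb(i, j);
    if (t == 0) break;
    if (t == 1) { ++aligned; --i; --j; }
    else if (t == 2) { --i; }
    else { --j; }
  }
  return List::create(_["score"] = best, _["aligned_cols"] = aligned,
                      _["i_range"] = IntegerVector::create(i + 1, ai_end),
                      _["j_range"] = IntegerVector::create(j + 1, aj_end));
}

// Affine-gap global alignment (Needleman-Wunsch/Gotoh) over a score
// matrix; returns the optimal score and the path as a vector of moves
// (1 diag, 2 up/gap-in-B, 3 left/gap-in-A) from start to end.
// [[Rcpp::export]]
List align_matrix_global(NumericMatrix S, double gap_open, double gap_extend) {
  int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  H(0, 0) = 0; E(0, 0) = NEG; F(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    F(i, 0) = -gap_open - (i - 1) * gap_extend;
    H(i, 0) = F(i, 0); E(i, 0) = NEG;
  }
  for (int j = 1; j <= m; ++j) {
    E(0, j) = -gap_open - (j - 1) * gap_extend;
    H(0, j) = E(0, j); F(0, j) = NEG;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E(i, j) = std::max(H(i, j - 1) - gap_open, E(i, j - 1) - gap_extend);
      F(i, j) = std::max(H(i - 1, j) - gap_open, F(i - 1, j) - gap_extend);
      double diag = H(i - 1, j - 1) + S(i - 1, j - 1);
      double h = diag;
      if (F(i, j) > h) h = F(i, j);
      if (E(i, j) > h) h = E(i, j);
      H(i, j) = h;
    }
  }
  // traceback (prefer diag, then up, then left on ties)
  std::vector<int> path;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        std::abs(H(i, j) - (H(i - 1, j - 1) + S(i - 1, j - 1))) < 1e-9) {
      path.push_back(1); --i; --j;
    } else if (i > 0 && std::abs(H(i, j) - F(i, j)) < 1e-9) {
      // walk the gap run
      while (i > 1 && std::abs(F(i, j) - (F(i - 1, j) - gap_extend)) < 1e-9 &&
             !(std::abs(F(i, j) - (H(i - 1, j) - gap_open)) < 1e-9)) {
        path.push_back(2); --i;
      }
      path.push_back(2); --i;
    } else if (j > 0) {
      while (j > 1 && std::abs(E(i, j) - (E(i, j - 1) - gap_extend)) < 1e-9 &&
             !(std::abs(E(i, j) - (H(i, j - 1) - gap_open)) < 1e-9)) {
        path.push_back(3); --j;
      }
      path.push_back(3); --j;
    } else {
      path.push_back(2); --i;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = H(n, m), _["path"] = wrap(path));
}
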