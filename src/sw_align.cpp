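#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman local alignment with a fixed, documented
// traceback so identity/coverage are deterministic even when several
// alignments share the optimal score.
//
// Conventions (mirrored by the plain-R oracle in the test suite):
//  * a gap of length k costs gap_open + k * gap_ext (BLAST-style
//    existence + per-column extension);
//  * the end cell is the highest-scoring (i, j), ties broken by smaller
//    i then smaller j;
//  * in H, preference is diagonal, then vertical (gap in b), then
//    horizontal (gap in a); in E/F, closing the gap (re-entering H) is
//    preferred over extending it.

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b,
                  NumericMatrix score, double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e18;
  // full DP matrices (sequences here are proteins, at most a few kb)
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  IntegerMatrix TH(n + 1, m + 1);  // 0 stop, 1 diag, 2 from F, 3 from E
  IntegerMatrix TE(n + 1, m + 1);  // 1 opened from H, 0 extended
  IntegerMatrix TF(n + 1, m + 1);

  for (int j = 0; j <= m; ++j) { E(0, j) = F(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { E(i, 0) = F(i, 0) = NEG; }

  double best = 0.0; int bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double e_open = H(i, j - 1) - gap_open - gap_ext;
      double e_ext  = E(i, j - 1) - gap_ext;
      if (e_open >= e_ext) { E(i, j) = e_open; TE(i, j) = 1; }
      else                 { E(i, j) = e_ext;  TE(i, j) = 0; }

      double f_open = H(i - 1, j) - gap_open - gap_ext;
      double f_ext  = F(i - 1, j) - gap_ext;
      if (f_open >= f_ext) { F(i, j) = f_open; TF(i, j) = 1; }
      else                 { F(i, j) = f_ext;  TF(i, j) = 0; }

      double diag = H(i - 1, j - 1) + score(a[i - 1] - 1, b[j - 1] - 1);
      double h = 0.0; int t = 0;
      if (diag >= h) { h = diag; t = 1; }
      if (F(i, j) > h) { h = F(i, j); t = 2; }
      if (E(i, j) > h) { h = E(i, j); t = 3; }
      H(i, j) = h; TH(i, j) = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  int matches = 0, columns = 0, a_cols = 0, b_cols = 0;
  int a_start = 0, a_end = 0, b_start = 0, b_end = 0;
  if (best > 0.0) {
    int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
    a_end = bi; b_end = bj;
    while (true) {
      if (state == 0) {
        int t = TH(i, j);
        if (t == 0) break;
        if (t == 1) {
          ++columns; ++a_cols; ++b_cols;
          if (a[i - 1] == b[j - 1]) ++matches;
          --i; --j;
        } else if (t == 2) {
          state = 2;
        } else {
          state = 1;
        }
      } else if (state == 1) {      // gap in a, consume b[j]
        ++columns; ++b_cols;
        int t = TE(i, j);
        --j;
        state = (t == 1) ? 0 : 1;
      } else {                      // gap in b, consume a[i]
        ++columns; ++a_cols;
        int t = TF(i, j);
        --i;
        state = (t == 1) ? 0 : 2;
      }
    }
    a_start = i; b_start = j;       // 0-based starts
  }
  return List::create(
    _["score"] = best, _["matches"] = matches, _["columns"] = columns,
    _["a_cols"] = a_cols, _["b_cols"] = b_cols,
    _["a_start"] = a_start, _["a_end"] = a_end,
    _["b_start"] = b_start, _["b_end"] = b_end);
}
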