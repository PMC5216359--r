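#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap global alignment over a precomputed score matrix.
//
// S(i, j) holds the score for pairing item i of sequence/profile A with
// item j of B; gaps cost gap_open for the first gapped position and
// gap_ext for each further position of the same gap.  With
// free_ends = true, terminal gaps on either sequence are free
// (semi-global alignment).  Ties are resolved deterministically:
// diagonal is preferred over a gap in B, which is preferred over a gap
// in A, so equal-score alternatives collapse onto one canonical path.
//
// Returns the aligned index paths (0 marks a gap) and the total score.
// [[Rcpp::export]]
List gotoh_path_cpp(NumericMatrix S, double gap_open, double gap_ext,
                    bool free_ends) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix bM(n + 1, m + 1), bX(n + 1, m + 1), bY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; i++) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = free_ends ? 0.0 : gap_open + (i - 1) * gap_ext;
    bX(i, 0) = 1;
  }
  for (int j = 1; j <= m; j++) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = free_ends ? 0.0 : gap_open + (j - 1) * gap_ext;
    bY(0, j) = 2;
  }

  for (int i = 1; i <= n; i++) {
    for (int j = 1; j <= m; j++) {
      double a = M(i - 1, j - 1), b = X(i - 1, j - 1), c = Y(i - 1, j - 1);
      int w = 0; double best = a;
      if (b > best) { best = b; w = 1; }
      if (c > best) { best = c; w = 2; }
      M(i, j) = best + S(i - 1, j - 1); bM(i, j) = w;

      // gap in B (consumes A); free when hugging the right border
      double go = (free_ends && j == m) ? 0.0 : gap_open;
      double ge = (free_ends && j == m) ? 0.0 : gap_ext;
      double fM = M(i - 1, j) + go, fX = X(i - 1, j) + ge;
      if (fM >= fX) { X(i, j) = fM; bX(i, j) = 0; }
      else          { X(i, j) = fX; bX(i, j) = 1; }

      // gap in A (consumes B); free when hugging the bottom border
      double go2 = (free_ends && i == n) ? 0.0 : gap_open;
      double ge2 = (free_ends && i == n) ? 0.0 : gap_ext;
      double fM2 = M(i, j - 1) + go2, fY = Y(i, j - 1) + ge2;
      if (fM2 >= fY) { Y(i, j) = fM2; bY(i, j) = 0; }
      else           { Y(i, j) = fY;  bY(i, j) = 2; }
    }
  }

  int cur = 0; double best = M(n, m);
  if (X(n, m) > best) { best = X(n, m); cur = 1; }
  if (Y(n, m) > best) { best = Y(n, m); cur = 2; }

  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (cur == 0) {
      ai.push_back(i); bi.push_back(j);
      cur = bM(i, j); i--; j--;
    } else if (cur == 1) {
      ai.push_back(i); bi.push_back(0);
      cur = bX(i, j); i--;
    } else {
      ai.push_back(0); bi.push_back(j);
      cur = bY(i, j); j--;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bi),
                      _["score"] = best);
}

// Pairwise site-pattern counts for the Kimura 2-parameter distance.
//
// X codes each sequence (row) over alignment columns: 1=A, 2=C, 3=G,
// 4=T, 0 = anything else (gap or ambiguity code, excluded pairwise).
// With this coding a substitution is a transition iff |a - b| == 2
// (A<->G is 1<->3, C<->T is 2<->4).  Returns symmetric matrices of
// comparable sites (n), transitions (s) and transversions (v).
// [[Rcpp::export]]
List k2p_counts_cpp(IntegerMatrix X) {
  const int ns = X.nrow(), L = X.ncol();
  IntegerMatrix n(ns, ns), s(ns, ns), v(ns, ns);
  for (int a = 0; a < ns; a++) {
    for (int b = a + 1; b < ns; b++) {
      int nn = 0, ss = 0, vv = 0;
      for (int k = 0; k < L; k++) {
        const int xa = X(a, k), xb = X(b, k);
        if (xa == 0 || xb == 0) continue;
        nn++;
        if (xa != xb) {
          int d = xa - xb; if (d < 0) d = -d;
          if (d == 2) ss++; else vv++;
        }
      }
      n(a, b) = n(b, a) = nn;
      s(a, b) = s(b, a) = ss;
      v(a, b) = v(b, a) = vv;
    }
  }
  return List::create(_["n"] = n, _["s"] = s, _["v"] = v);
}

// Semi-global (free end gaps) Needleman-Wunsch identity between two
// ungapped sequences with a linear gap penalty. Returns the number of
// matches and aligned columns on the optimal path, excluding terminal
// overhangs (the path is traced from the best cell on the last
// row/column back to the first row/column). Used by identity_percent,
// where thousands of query-vs-reference comparisons are made.
// [[Rcpp::export]]
List nw_identity_cpp(std::string a, std::string b, double match,
                     double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  NumericMatrix M(n + 1, m + 1);
  for (int i = 0; i <= n; i++) M(i, 0) = 0.0;
  for (int j = 0; j <= m; j++) M(0, j) = 0.0;
  for (int i = 1; i <= n; i++) {
    for (int j = 1; j <= m; j++) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double best = M(i - 1, j - 1) + s;
      double up = M(i - 1, j) + gap;
      double left = M(i, j - 1) + gap;
      if (up > best) best = up;
      if (left > best) best = left;
      M(i, j) = best;
    }
  }
  // best end on the last row or column (free trailing gaps)
  int ei = n, ej = m; double bestv = M(n, m);
  for (int j = 0; j <= m; j++) {
    if (M(n, j) > bestv) { bestv = M(n, j); ei = n; ej = j; }
  }
  for (int i = 0; i <= n; i++) {
    if (M(i, m) > bestv) { bestv = M(i, m); ei = i; ej = m; }
  }
  int i = ei, j = ej, matches = 0, cols = 0;
  while (i > 0 && j > 0) {
    double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
    if (M(i, j) == M(i - 1, j - 1) + s) {
      cols++; if (a[i - 1] == b[j - 1]) matches++;
      i--; j--;
    } else if (M(i, j) == M(i - 1, j) + gap) {
      cols++; i--;
    } else {
      cols++; j--;
    }
  }
  return List::create(_["matches"] = matches, _["columns"] = cols);
}
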