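#include <Rcpp.h>
using namespace Rcpp;

// Global (end-to-end) affine-gap alignment of a query sequence against a
// fixed column profile, Gotoh three-state recursion.  colscores[i, j] is
// the expected substitution score of query residue i against profile
// column j (precomputed in R).  Ties are broken deterministically with
// preference match > delete > insert, where "delete" consumes a profile
// column (gap in the query row) and "insert" consumes a query residue
// (inserted column relative to the profile).
//
// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix colscores, double gap_open,
                       double gap_extend) {
  const int m = colscores.nrow();  // query residues
  const int n = colscores.ncol();  // profile columns
  const double NEG = -1e18;

  NumericMatrix M(m + 1, n + 1), X(m + 1, n + 1), Y(m + 1, n + 1);
  IntegerMatrix tM(m + 1, n + 1), tX(m + 1, n + 1), tY(m + 1, n + 1);
  // traceback codes: 0 = from M, 1 = from X (delete), 2 = from Y (insert)

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int j = 1; j <= n; ++j) {
    M(0, j) = NEG; Y(0, j) = NEG;
    X(0, j) = -gap_open - (j - 1) * gap_extend;
    tX(0, j) = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= m; ++i) {
    M(i, 0) = NEG; X(i, 0) = NEG;
    Y(i, 0) = -gap_open - (i - 1) * gap_extend;
    tY(i, 0) = (i == 1) ? 0 : 2;
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // match state
      double bm = M(i - 1, j - 1), bx = X(i - 1, j - 1), by = Y(i - 1, j - 1);
      int arg = 0; double best = bm;
      if (bx > best) { best = bx; arg = 1; }
      if (by > best) { best = by; arg = 2; }
      M(i, j) = best + colscores(i - 1, j - 1);
      tM(i, j) = arg;

      // delete state: gap in query row, consume column j
      double dm = M(i, j - 1) - gap_open;
      double dx = X(i, j - 1) - gap_extend;
      double dy = Y(i, j - 1) - gap_open;
      arg = 0; best = dm;
      if (dx > best) { best = dx; arg = 1; }
      if (dy > best) { best = dy; arg = 2; }
      X(i, j) = best; tX(i, j) = arg;

      // insert state: query residue i inserted
      double im = M(i - 1, j) - gap_open;
      double ix = X(i - 1, j) - gap_open;
      double iy = Y(i - 1, j) - gap_extend;
      arg = 0; best = im;
      if (ix > best) { best = ix; arg = 1; }
      if (iy > best) { best = iy; arg = 2; }
      Y(i, j) = best; tY(i, j) = arg;
    }
  }

  int state = 0;
  double score = M(m, n);
  if (X(m, n) > score) { score = X(m, n); state = 1; }
  if (Y(m, n) > score) { score = Y(m, n); state = 2; }

  // traceback
  std::string moves;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tM(i, j);
      moves.push_back('M');
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tX(i, j);
      moves.push_back('D');
      --j; state = prev;
    } else {
      int prev = tY(i, j);
      moves.push_back('I');
      --i; state = prev;
    }
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(_["score"] = score, _["moves"] = moves);
}
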