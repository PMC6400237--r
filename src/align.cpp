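#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh) over a precomputed cell-score matrix.
// cell(i-1, j-1) scores pairing row-unit i with column-unit j, so the same
// kernel serves residue-residue and profile-profile alignment.  A gap of
// length k costs gap_open + k * gap_extend (both passed as non-negative).
//
// Returns list(score, path); path is the move sequence from the alignment
// start: 0 = diagonal (consume one unit of each side), 1 = gap in the row
// side (consume a column unit), 2 = gap in the column side (consume a row
// unit).  Traceback ties prefer diagonal, then gap-in-row-side, then
// gap-in-column-side, making the alignment deterministic.
// [[Rcpp::export(name = ".affine_dp")]]
List affine_dp(NumericMatrix cell, double gap_open, double gap_extend) {
  const int n = cell.nrow(), m = cell.ncol();
  if (n < 1 || m < 1) stop("cell score matrix must be non-empty");
  const double NEG = -1e300;
  const double open1 = gap_open + gap_extend;  // first residue of a gap

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // X: gap in the row side (horizontal move), Y: gap in the column side.
  M(0, 0) = 0.0;
  X(0, 0) = Y(0, 0) = NEG;
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG;
    Y(0, j) = NEG;
    X(0, j) = -(gap_open + j * gap_extend);
  }
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG;
    X(i, 0) = NEG;
    Y(i, 0) = -(gap_open + i * gap_extend);
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double dm = M(i - 1, j - 1), dx = X(i - 1, j - 1), dy = Y(i - 1, j - 1);
      M(i, j) = std::max(dm, std::max(dx, dy)) + cell(i - 1, j - 1);

      double xm = M(i, j - 1) - open1;
      double xx = X(i, j - 1) - gap_extend;
      double xy = Y(i, j - 1) - open1;
      X(i, j) = std::max(xm, std::max(xx, xy));

      double ym = M(i - 1, j) - open1;
      double yx = X(i - 1, j) - open1;
      double yy = Y(i - 1, j) - gap_extend;
      Y(i, j) = std::max(ym, std::max(yx, yy));
    }
  }

  // End state: prefer M, then X, then Y on ties.
  int state = 0;
  double score = M(n, m);
  if (X(n, m) > score) { score = X(n, m); state = 1; }
  if (Y(n, m) > score) { score = Y(n, m); state = 2; }

  std::vector<int> rev;
  rev.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) { rev.push_back(1); --j; continue; }  // forced along top edge
    if (j == 0) { rev.push_back(2); --i; continue; }  // forced along left edge
    if (state == 0) {
      rev.push_back(0);
      double dm = M(i - 1, j - 1), dx = X(i - 1, j - 1), dy = Y(i - 1, j - 1);
      double best = std::max(dm, std::max(dx, dy));
      state = (dm >= best) ? 0 : ((dx >= best) ? 1 : 2);
      --i; --j;
    } else if (state == 1) {
      rev.push_back(1);
      double xm = M(i, j - 1) - open1;
      double xx = X(i, j - 1) - gap_extend;
      double xy = Y(i, j - 1) - open1;
      double best = std::max(xm, std::max(xx, xy));
      state = (xm >= best) ? 0 : ((xx >= best) ? 1 : 2);
      --j;
    } else {
      rev.push_back(2);
      double ym = M(i - 1, j) - open1;
      double yx = X(i - 1, j) - open1;
      double yy = Y(i - 1, j) - gap_extend;
      double best = std::max(ym, std::max(yx, yy));
      state = (ym >= best) ? 0 : ((yx >= best) ? 1 : 2);
      --i;
    }
  }
  std::reverse(rev.begin(), rev.end());
  return List::create(_["score"] = score, _["path"] = IntegerVector(rev.begin(), rev.end()));
}
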