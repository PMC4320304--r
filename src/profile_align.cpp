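#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment of two profiles under affine gaps.
// `colscore` holds the pre-computed expected substitution score between every
// column of profile A (rows) and profile B (columns); gap costs are applied
// per aligned column, not occupancy-weighted. Tie-break order is fixed
// (diagonal, then gap-in-B, then gap-in-A) so the alignment is deterministic.
//
// Returns two integer vectors of equal length: the A column index and the B
// column index consumed at each output column, 0 where the column is a gap.
// [[Rcpp::export(name = ".nw_profile_path")]]
List nw_profile_path(NumericMatrix colscore, double gap_open, double gap_ext) {
  const int n = colscore.nrow(), m = colscore.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();
  // state 0 = M (diag), 1 = X (consume A, gap in B), 2 = Y (consume B, gap in A)
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG)),
      X(n + 1, std::vector<double>(m + 1, NEG)),
      Y(n + 1, std::vector<double>(m + 1, NEG));
  // pointers: which state we came from (0/1/2)
  std::vector<std::vector<signed char>> pm(n + 1, std::vector<signed char>(m + 1, -1)),
      px(n + 1, std::vector<signed char>(m + 1, -1)),
      py(n + 1, std::vector<signed char>(m + 1, -1));

  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    double from_m = M[i - 1][0] - gap_open - gap_ext, from_x = X[i - 1][0] - gap_ext;
    if (from_m >= from_x) { X[i][0] = from_m; px[i][0] = 0; }
    else                  { X[i][0] = from_x; px[i][0] = 1; }
  }
  for (int j = 1; j <= m; ++j) {
    double from_m = M[0][j - 1] - gap_open - gap_ext, from_y = Y[0][j - 1] - gap_ext;
    if (from_m >= from_y) { Y[0][j] = from_m; py[0][j] = 0; }
    else                  { Y[0][j] = from_y; py[0][j] = 2; }
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: diagonal
      double best = M[i - 1][j - 1]; signed char arg = 0;
      if (X[i - 1][j - 1] > best) { best = X[i - 1][j - 1]; arg = 1; }
      if (Y[i - 1][j - 1] > best) { best = Y[i - 1][j - 1]; arg = 2; }
      M[i][j] = best + colscore(i - 1, j - 1); pm[i][j] = arg;
      // X: consume A row i, gap in B
      double xo = std::max(M[i - 1][j], Y[i - 1][j]) - gap_open - gap_ext;
      double xe = X[i - 1][j] - gap_ext;
      if (xo >= xe) { X[i][j] = xo; px[i][j] = (M[i - 1][j] >= Y[i - 1][j]) ? 0 : 2; }
      else          { X[i][j] = xe; px[i][j] = 1; }
      // Y: consume B col j, gap in A
      double yo = std::max(M[i][j - 1], X[i][j - 1]) - gap_open - gap_ext;
      double ye = Y[i][j - 1] - gap_ext;
      if (yo >= ye) { Y[i][j] = yo; py[i][j] = (M[i][j - 1] >= X[i][j - 1]) ? 0 : 1; }
      else          { Y[i][j] = ye; py[i][j] = 2; }
    }
  }
  int state = 0;
  double sc = M[n][m];
  if (X[n][m] > sc) { sc = X[n][m]; state = 1; }
  if (Y[n][m] > sc) { sc = Y[n][m]; state = 2; }

  std::vector<int> ai, bj;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ai.push_back(i); bj.push_back(j);
      state = pm[i][j]; --i; --j;
    } else if (state == 1) {
      ai.push_back(i); bj.push_back(0);
      state = px[i][j]; --i;
    } else {
      ai.push_back(0); bj.push_back(j);
      state = py[i][j]; --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bj.begin(), bj.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bj), _["score"] = sc);
}
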