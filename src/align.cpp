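#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap (Gotoh) alignment over a precomputed column-pair score
// matrix S (n1 x n2): S(i,j) is the score of aligning column i of profile 1
// with column j of profile 2. Returns the traceback as a vector of moves:
// 1 = diagonal (consume a column of both profiles),
// 2 = up   (consume profile-1 column, gap in profile 2),
// 3 = left (consume profile-2 column, gap in profile 1).
// gap_open is the cost of the first gap position, gap_ext of each further one.
// [[Rcpp::export]]
IntegerVector gotoh_global(const NumericMatrix& S, double gap_open, double gap_ext) {
  const int n1 = S.nrow(), n2 = S.ncol();
  const double NEG = -1e30;
  // DP matrices: M = match state, X = gap in profile 2 (vertical),
  // Y = gap in profile 1 (horizontal).
  std::vector<double> M((n1 + 1) * (n2 + 1), NEG), X(M), Y(M);
  std::vector<signed char> tM(M.size(), 0), tX(M.size(), 0), tY(M.size(), 0);
  auto at = [n2](int i, int j) { return i * (n2 + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n1; ++i) {
    X[at(i, 0)] = -gap_open - gap_ext * (i - 1);
    tX[at(i, 0)] = (i == 1) ? 1 : 2; // came from M at origin, else extend
  }
  for (int j = 1; j <= n2; ++j) {
    Y[at(0, j)] = -gap_open - gap_ext * (j - 1);
    tY[at(0, j)] = (j == 1) ? 1 : 2;
  }
  for (int i = 1; i <= n1; ++i) {
    for (int j = 1; j <= n2; ++j) {
      const int ij = at(i, j), d = at(i - 1, j - 1), u = at(i - 1, j), l = at(i, j - 1);
      // M
      double best = M[d]; signed char tb = 1;
      if (X[d] > best) { best = X[d]; tb = 2; }
      if (Y[d] > best) { best = Y[d]; tb = 3; }
      M[ij] = best + S(i - 1, j - 1); tM[ij] = tb;
      // X: gap in profile 2 (move up)
      double xo = M[u] - gap_open, xe = X[u] - gap_ext, yo = Y[u] - gap_open;
      if (xo >= xe && xo >= yo) { X[ij] = xo; tX[ij] = 1; }
      else if (xe >= yo)        { X[ij] = xe; tX[ij] = 2; }
      else                      { X[ij] = yo; tX[ij] = 3; }
      // Y: gap in profile 1 (move left)
      double ym = M[l] - gap_open, yx = X[l] - gap_open, ye = Y[l] - gap_ext;
      if (ym >= ye && ym >= yx) { Y[ij] = ym; tY[ij] = 1; }
      else if (ye >= yx)        { Y[ij] = ye; tY[ij] = 2; }
      else                      { Y[ij] = yx; tY[ij] = 3; }
    }
  }
  // traceback from best end state
  int i = n1, j = n2, state;
  const int e = at(n1, n2);
  if (M[e] >= X[e] && M[e] >= Y[e]) state = 1;
  else if (X[e] >= Y[e]) state = 2;
  else state = 3;
  std::vector<int> moves;
  while (i > 0 || j > 0) {
    const int ij = at(i, j);
    if (state == 1 && i > 0 && j > 0) {
      moves.push_back(1); state = tM[ij]; --i; --j;
    } else if (state == 2 && i > 0) {
      moves.push_back(2); state = tX[ij]; --i;
    } else if (state == 3 && j > 0) {
      moves.push_back(3); state = tY[ij]; --j;
    } else {
      // boundary: forced direction
      if (i > 0) { moves.push_back(2); --i; state = 2; }
      else       { moves.push_back(3); --j; state = 3; }
    }
  }
  std::reverse(moves.begin(), moves.end());
  return wrap(moves);
}
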