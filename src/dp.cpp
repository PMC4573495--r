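#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static const double NEG = -1e18;

// Global Needleman-Wunsch with affine gaps over a precomputed column-pair
// score matrix S (n1 x n2). A gap of length L costs gapOpen + L * gapExt.
// Returns the optimal score and the traceback as moves:
// 1 = diagonal, 2 = consume row profile only, 3 = consume column profile only.
// [[Rcpp::export]]
List nwProfileAlign(NumericMatrix S, double gapOpen, double gapExt) {
  int n = S.nrow(), m = S.ncol();
  double openCost = gapOpen + gapExt;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix pm(n + 1, m + 1), px(n + 1, m + 1), py(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = NEG; X(i, j) = NEG; Y(i, j) = NEG; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) {
    X(i, 0) = -(gapOpen + i * gapExt);
    px(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y(0, j) = -(gapOpen + j * gapExt);
    py(0, j) = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M
      double d = M(i - 1, j - 1); int st = 0;
      if (X(i - 1, j - 1) > d) { d = X(i - 1, j - 1); st = 1; }
      if (Y(i - 1, j - 1) > d) { d = Y(i - 1, j - 1); st = 2; }
      M(i, j) = d + S(i - 1, j - 1); pm(i, j) = st;
      // X: gap consuming row profile
      double x = M(i - 1, j) - openCost; st = 0;
      if (X(i - 1, j) - gapExt > x) { x = X(i - 1, j) - gapExt; st = 1; }
      if (Y(i - 1, j) - openCost > x) { x = Y(i - 1, j) - openCost; st = 2; }
      X(i, j) = x; px(i, j) = st;
      // Y: gap consuming column profile
      double y = M(i, j - 1) - openCost; st = 0;
      if (Y(i, j - 1) - gapExt > y) { y = Y(i, j - 1) - gapExt; st = 2; }
      if (X(i, j - 1) - openCost > y) { y = X(i, j - 1) - openCost; st = 1; }
      Y(i, j) = y; py(i, j) = st;
    }
  }
  int state = 0;
  double best = M(n, m);
  if (X(n, m) > best) { best = X(n, m); state = 1; }
  if (Y(n, m) > best) { best = Y(n, m); state = 2; }
  std::vector<int> moves;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      moves.push_back(1); state = pm(i, j); --i; --j;
    } else if (state == 1) {
      moves.push_back(2); state = px(i, j); --i;
    } else {
      moves.push_back(3); state = py(i, j); --j;
    }
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(Named("score") = best,
                      Named("moves") = IntegerVector(moves.begin(), moves.end()));
}

// Three-frame protein-to-nucleotide alignment with frameshift transitions.
// S is an n x m matrix: S(i-1, j-1) scores the codon ENDING at nucleotide i
// against reference residue j (rows i < 3 are never read). The locus is
// aligned quasi-globally -- at most two unaligned nucleotides are free at
// each end -- while reference prefix/suffix gaps are free. Moves consuming a
// reference residue: 1 = 3-nt codon, 2 = 2-nt (frameshift), 3 = 4-nt
// (frameshift); 4 = codon deleted relative to the reference; 5 = reference
// residue skipped. Each move 2 or 3 counts one frameshift event.
// [[Rcpp::export]]
List frameshiftAlignC(NumericMatrix S, double fsPenalty, double gapAA,
                      double gapCodon) {
  int n = S.nrow(), m = S.ncol();
  if (n < 3) stop("locus shorter than one codon");
  NumericMatrix D(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { D(i, j) = NEG; P(i, j) = 0; }
  for (int i = 0; i <= std::min(2, n); ++i)
    for (int j = 0; j <= m; ++j) D(i, j) = 0.0;   // start states
  for (int i = 3; i <= n; ++i) {                   // j = 0 column
    D(i, 0) = D(i - 3, 0) - gapCodon;
    P(i, 0) = 4;
  }
  for (int i = 3; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = S(i - 1, j - 1);
      double best = D(i - 3, j - 1) + s; int mv = 1;
      double c2 = D(i - 2, j - 1) + s - fsPenalty;
      if (c2 > best) { best = c2; mv = 2; }
      if (i >= 4) {
        double c3 = D(i - 4, j - 1) + s - fsPenalty;
        if (c3 > best) { best = c3; mv = 3; }
      }
      double c4 = D(i - 3, j) - gapCodon;
      if (c4 > best) { best = c4; mv = 4; }
      double c5 = D(i, j - 1) - gapAA;
      if (c5 > best) { best = c5; mv = 5; }
      D(i, j) = best; P(i, j) = mv;
    }
  }
  // free reference suffix; up to two trailing nucleotides free
  double best = NEG; int bi = n, bj = 0;
  for (int i = std::max(0, n - 2); i <= n; ++i)
    for (int j = 0; j <= m; ++j)
      if (D(i, j) > best) { best = D(i, j); bi = i; bj = j; }
  std::vector<int> ii, jj, mm;
  int i = bi, j = bj;
  while (true) {
    int mv = P(i, j);
    if (mv == 0) break;
    ii.push_back(i); jj.push_back(j); mm.push_back(mv);
    switch (mv) {
      case 1: i -= 3; --j; break;
      case 2: i -= 2; --j; break;
      case 3: i -= 4; --j; break;
      case 4: i -= 3; break;
      case 5: --j; break;
    }
  }
  int L = (int) ii.size();
  IntegerMatrix path(L, 3);
  for (int r = 0; r < L; ++r) {
    path(r, 0) = ii[L - 1 - r];
    path(r, 1) = jj[L - 1 - r];
    path(r, 2) = mm[L - 1 - r];
  }
  colnames(path) = CharacterVector::create("i", "j", "move");
  return List::create(Named("score") = best, Named("path") = path,
                      Named("end_i") = bi, Named("end_j") = bj);
}
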