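#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap alignment over a precomputed cell score matrix S (n1 x n2).
// A gap of length k costs gap_open + k * gap_ext (BLAST convention, so the
// first gapped position costs gap_open + gap_ext).  local = Smith-Waterman
// semantics (best-scoring subpath, score >= 0); otherwise global
// Needleman-Wunsch with penalized end gaps.
//
// Returns score, 1-based start/end in each dimension, and the alignment path
// as two integer vectors (0 marks a gap in that row).
// [[Rcpp::export]]
List align_score_matrix_cpp(NumericMatrix S, double gap_open, double gap_ext,
                            bool local) {
  const int n1 = S.nrow(), n2 = S.ncol();
  const double NEG = -1e30;
  const double open1 = gap_open + gap_ext;  // cost of opening a length-1 gap

  // row-major copy of S so the inner loop over j is cache-friendly
  std::vector<double> Sv((size_t)n1 * n2);
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i)
      Sv[(size_t)i * n2 + j] = S(i, j);

  // DP matrices: M ends in a match/mismatch, X consumes i (gap in dim 2),
  // Y consumes j (gap in dim 1).  Pointers: 0 diagM 1 diagX 2 diagY 3 stop,
  // for X: 0 fromM 1 extend; same for Y.
  std::vector<double> M((n1 + 1) * (n2 + 1), NEG);
  std::vector<double> X((n1 + 1) * (n2 + 1), NEG);
  std::vector<double> Y((n1 + 1) * (n2 + 1), NEG);
  std::vector<unsigned char> pM((n1 + 1) * (n2 + 1), 3);
  std::vector<unsigned char> pX((n1 + 1) * (n2 + 1), 0);
  std::vector<unsigned char> pY((n1 + 1) * (n2 + 1), 0);
  const int W = n2 + 1;
#define IDX(i, j) ((i) * W + (j))

  M[IDX(0, 0)] = 0.0;
  if (!local) {
    for (int i = 1; i <= n1; ++i) {
      X[IDX(i, 0)] = -(gap_open + i * gap_ext);
      pX[IDX(i, 0)] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= n2; ++j) {
      Y[IDX(0, j)] = -(gap_open + j * gap_ext);
      pY[IDX(0, j)] = (j == 1) ? 0 : 1;
    }
  }

  double best = local ? 0.0 : NEG;
  int bi = 0, bj = 0;
  char bmat = 'M';

  for (int i = 1; i <= n1; ++i) {
    for (int j = 1; j <= n2; ++j) {
      const int c = IDX(i, j), d = IDX(i - 1, j - 1);
      const int u = IDX(i - 1, j), l = IDX(i, j - 1);
      // M
      double m = M[d], x = X[d], y = Y[d];
      double vm = m;
      unsigned char pm = 0;
      if (x > vm) { vm = x; pm = 1; }
      if (y > vm) { vm = y; pm = 2; }
      if (local && vm < 0.0) { vm = 0.0; pm = 3; }
      vm = (vm <= NEG / 2) ? NEG : vm + Sv[(size_t)(i - 1) * n2 + (j - 1)];
      M[c] = vm;
      pM[c] = pm;
      // X (consume i)
      double xm = (M[u] <= NEG / 2) ? NEG : M[u] - open1;
      double xx = (X[u] <= NEG / 2) ? NEG : X[u] - gap_ext;
      if (xm >= xx) { X[c] = xm; pX[c] = 0; } else { X[c] = xx; pX[c] = 1; }
      // Y (consume j)
      double ym = (M[l] <= NEG / 2) ? NEG : M[l] - open1;
      double yy = (Y[l] <= NEG / 2) ? NEG : Y[l] - gap_ext;
      if (ym >= yy) { Y[c] = ym; pY[c] = 0; } else { Y[c] = yy; pY[c] = 1; }

      if (local && M[c] > best) { best = M[c]; bi = i; bj = j; bmat = 'M'; }
    }
  }

  if (!local) {
    bi = n1; bj = n2;
    const int c = IDX(n1, n2);
    best = M[c]; bmat = 'M';
    if (X[c] > best) { best = X[c]; bmat = 'X'; }
    if (Y[c] > best) { best = Y[c]; bmat = 'Y'; }
  }

  // Traceback
  std::vector<int> pi, pj;
  int i = bi, j = bj;
  char mat = bmat;
  if (local && best <= 0.0) {
    // empty local alignment
    return List::create(_["score"] = 0.0, _["i_start"] = 0, _["i_end"] = 0,
                        _["j_start"] = 0, _["j_end"] = 0,
                        _["path_i"] = IntegerVector(0),
                        _["path_j"] = IntegerVector(0));
  }
  while (i > 0 || j > 0) {
    const int c = IDX(i, j);
    if (mat == 'M') {
      pi.push_back(i); pj.push_back(j);
      const unsigned char p = pM[c];
      --i; --j;
      if (p == 3) break;  // local restart: alignment starts here
      mat = (p == 0) ? 'M' : (p == 1) ? 'X' : 'Y';
    } else if (mat == 'X') {
      pi.push_back(i); pj.push_back(0);
      const unsigned char p = pX[c];
      --i;
      mat = (p == 0) ? 'M' : 'X';
    } else {  // Y
      pi.push_back(0); pj.push_back(j);
      const unsigned char p = pY[c];
      --j;
      mat = (p == 0) ? 'M' : 'Y';
    }
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());

  int i1 = 0, i2 = 0, j1 = 0, j2 = 0;
  for (size_t k = 0; k < pi.size(); ++k) {
    if (pi[k] > 0) { if (i1 == 0) i1 = pi[k]; i2 = pi[k]; }
    if (pj[k] > 0) { if (j1 == 0) j1 = pj[k]; j2 = pj[k]; }
  }
  return List::create(_["score"] = best, _["i_start"] = i1, _["i_end"] = i2,
                      _["j_start"] = j1, _["j_end"] = j2,
                      _["path_i"] = wrap(pi), _["path_j"] = wrap(pj));
#undef IDX
}

// Score-only local alignment (no traceback); used for null-distribution
// calibration where only the optimum matters.
// [[Rcpp::export]]
double local_score_cpp(NumericMatrix S, double gap_open, double gap_ext) {
  const int n1 = S.nrow(), n2 = S.ncol();
  const double NEG = -1e30;
  const double open1 = gap_open + gap_ext;
  std::vector<double> Sv((size_t)n1 * n2);
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i)
      Sv[(size_t)i * n2 + j] = S(i, j);
  std::vector<double> M(n2 + 1, 0.0), X(n2 + 1, NEG), Y(n2 + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n1; ++i) {
    double diagM = 0.0, diagX = NEG, diagY = NEG;  // cell (i-1, j-1)
    M[0] = 0.0; X[0] = NEG; Y[0] = NEG;
    for (int j = 1; j <= n2; ++j) {
      const double upM = M[j], upX = X[j];
      double vm = diagM;
      if (diagX > vm) vm = diagX;
      if (diagY > vm) vm = diagY;
      if (vm < 0.0) vm = 0.0;
      vm += Sv[(size_t)(i - 1) * n2 + (j - 1)];
      const double vx = std::max(upM - open1, upX - gap_ext);
      const double vy = std::max(M[j - 1] - open1, Y[j - 1] - gap_ext);
      diagM = M[j]; diagX = X[j]; diagY = Y[j];
      M[j] = vm; X[j] = vx; Y[j] = vy;
      if (vm > best) best = vm;
    }
  }
  return best;
}
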