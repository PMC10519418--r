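#include <Rcpp.h>
using namespace Rcpp;

// Profile-profile global alignment with affine gaps (Gotoh).
// Profiles are integer matrices, rows = sequences, cols = alignment columns;
// residue codes are 1-based indices into the substitution matrix S, 0 = gap.
// Column-pair score: mean substitution score over all residue pairs with both
// cells non-gap (gap cells contribute 0). Gap penalties are applied in full
// at every column, including terminal columns, for determinism.
//
// Returns two 0/1 vectors over the merged columns: whether profile A
// (resp. B) advances at that column.

// [[Rcpp::export]]
List align_profiles_cpp(IntegerMatrix A, IntegerMatrix B, NumericMatrix S,
                        double gap_open, double gap_ext) {
  const int n = A.ncol(), m = B.ncol();
  const int nA = A.nrow(), nB = B.nrow();
  const int K = S.nrow();

  // residue count profiles (K x cols)
  std::vector<double> cntA((size_t)K * n, 0.0), cntB((size_t)K * m, 0.0);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < nA; ++i) {
      int c = A(i, j);
      if (c > 0) cntA[(size_t)j * K + (c - 1)] += 1.0;
    }
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < nB; ++i) {
      int c = B(i, j);
      if (c > 0) cntB[(size_t)j * K + (c - 1)] += 1.0;
    }
  // TA = S %*% cntA (K x n)
  std::vector<double> TA((size_t)K * n, 0.0);
  for (int j = 0; j < n; ++j)
    for (int r = 0; r < K; ++r) {
      double acc = 0.0;
      for (int q = 0; q < K; ++q) acc += S(r, q) * cntA[(size_t)j * K + q];
      TA[(size_t)j * K + r] = acc;
    }
  const double denom = (double)nA * (double)nB;

  const double NEG = -1e18;
  std::vector<double> M((size_t)(n + 1) * (m + 1), NEG);
  std::vector<double> X((size_t)(n + 1) * (m + 1), NEG); // gap in B (A advances)
  std::vector<double> Y((size_t)(n + 1) * (m + 1), NEG); // gap in A (B advances)
  std::vector<unsigned char> tbM((size_t)(n + 1) * (m + 1), 0),
      tbX((size_t)(n + 1) * (m + 1), 0), tbY((size_t)(n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -gap_open - gap_ext * (i - 1);
    tbX[at(i, 0)] = 1; // came from X
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -gap_open - gap_ext * (j - 1);
    tbY[at(0, j)] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = 0.0;
      for (int r = 0; r < K; ++r)
        s += TA[(size_t)(i - 1) * K + r] * cntB[(size_t)(j - 1) * K + r];
      s /= denom;
      // M: diagonal from best of M/X/Y at (i-1, j-1); prefer M > X > Y
      double m0 = M[at(i - 1, j - 1)], x0 = X[at(i - 1, j - 1)],
             y0 = Y[at(i - 1, j - 1)];
      unsigned char from = 0;
      double best = m0;
      if (x0 > best) { best = x0; from = 1; }
      if (y0 > best) { best = y0; from = 2; }
      M[at(i, j)] = best + s;
      tbM[at(i, j)] = from;
      // X: A advances against gap; open from M, extend from X
      double xo = M[at(i - 1, j)] - gap_open, xe = X[at(i - 1, j)] - gap_ext;
      if (xo >= xe) { X[at(i, j)] = xo; tbX[at(i, j)] = 0; }
      else          { X[at(i, j)] = xe; tbX[at(i, j)] = 1; }
      // Y: B advances against gap
      double yo = M[at(i, j - 1)] - gap_open, ye = Y[at(i, j - 1)] - gap_ext;
      if (yo >= ye) { Y[at(i, j)] = yo; tbY[at(i, j)] = 0; }
      else          { Y[at(i, j)] = ye; tbY[at(i, j)] = 2; }
    }
  }

  // traceback from best of M/X/Y at (n, m); prefer M > X > Y
  int i = n, j = m;
  unsigned char state = 0;
  {
    double best = M[at(n, m)];
    if (X[at(n, m)] > best) { best = X[at(n, m)]; state = 1; }
    if (Y[at(n, m)] > best) { state = 2; }
  }
  std::vector<int> stepA, stepB;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char from = tbM[at(i, j)];
      stepA.push_back(1); stepB.push_back(1);
      --i; --j;
      state = from;
    } else if (state == 1) {
      unsigned char from = tbX[at(i, j)];
      stepA.push_back(1); stepB.push_back(0);
      --i;
      state = from;
    } else {
      unsigned char from = tbY[at(i, j)];
      stepA.push_back(0); stepB.push_back(1);
      --j;
      state = from;
    }
  }
  std::reverse(stepA.begin(), stepA.end());
  std::reverse(stepB.begin(), stepB.end());
  return List::create(_["a"] = wrap(stepA), _["b"] = wrap(stepB));
}
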