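#include <Rcpp.h>
using namespace Rcpp;

// Profile-profile global alignment with affine gaps (Gotoh). Profiles are
// 20 x L residue-frequency matrices; the score of pairing column i of A
// with column j of B is fA_i' S fB_j. Opening a gap of length k costs
// gapOpen + k * gapExt (matching the pairwise aligner's convention).
// Traceback tie-break: diagonal > up (gap in B) > left (gap in A).
//
// Returns two integer vectors mapping merged columns to source columns
// (0 = gap).
// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix A, NumericMatrix B, NumericMatrix S,
                       double gapOpen, double gapExt) {
  const int la = A.ncol(), lb = B.ncol(), na = A.nrow();
  const double NEG = -1e30;

  // Precompute SA = S' * A  (20 x la), cell score = dot(SA[,i], B[,j])
  std::vector<double> SA((size_t)na * la);
  for (int i = 0; i < la; ++i)
    for (int r = 0; r < na; ++r) {
      double acc = 0.0;
      for (int q = 0; q < na; ++q) acc += S(q, r) * A(q, i);
      SA[(size_t)i * na + r] = acc;
    }
  auto cell = [&](int i, int j) {
    double acc = 0.0;
    const double *sa = &SA[(size_t)(i - 1) * na];
    for (int r = 0; r < na; ++r) acc += sa[r] * B(r, j - 1);
    return acc;
  };

  // M: end in match; X: end with gap in B (consume A); Y: gap in A.
  std::vector<double> M((size_t)(la + 1) * (lb + 1), NEG),
      X((size_t)(la + 1) * (lb + 1), NEG), Y((size_t)(la + 1) * (lb + 1), NEG);
  std::vector<unsigned char> tbM((size_t)(la + 1) * (lb + 1)),
      tbX((size_t)(la + 1) * (lb + 1)), tbY((size_t)(la + 1) * (lb + 1));
  auto idx = [&](int i, int j) { return (size_t)i * (lb + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= la; ++i) {
    X[idx(i, 0)] = -gapOpen - gapExt * i;
    tbX[idx(i, 0)] = 1; // extend
  }
  for (int j = 1; j <= lb; ++j) {
    Y[idx(0, j)] = -gapOpen - gapExt * j;
    tbY[idx(0, j)] = 1;
  }

  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      double sc = cell(i, j);
      // M from best of M/X/Y at (i-1, j-1); tie-break M > X > Y
      double m0 = M[idx(i - 1, j - 1)], x0 = X[idx(i - 1, j - 1)],
             y0 = Y[idx(i - 1, j - 1)];
      double best = m0; unsigned char tb = 0;
      if (x0 > best) { best = x0; tb = 1; }
      if (y0 > best) { best = y0; tb = 2; }
      M[idx(i, j)] = best + sc; tbM[idx(i, j)] = tb;
      // X: gap in B, consume A column i
      double xo = M[idx(i - 1, j)] - gapOpen - gapExt;
      double xe = X[idx(i - 1, j)] - gapExt;
      if (xo >= xe) { X[idx(i, j)] = xo; tbX[idx(i, j)] = 0; }
      else          { X[idx(i, j)] = xe; tbX[idx(i, j)] = 1; }
      // Y: gap in A, consume B column j
      double yo = M[idx(i, j - 1)] - gapOpen - gapExt;
      double ye = Y[idx(i, j - 1)] - gapExt;
      if (yo >= ye) { Y[idx(i, j)] = yo; tbY[idx(i, j)] = 0; }
      else          { Y[idx(i, j)] = ye; tbY[idx(i, j)] = 1; }
    }
  }

  // Traceback from best terminal state (tie-break M > X > Y)
  int i = la, j = lb;
  double m0 = M[idx(i, j)], x0 = X[idx(i, j)], y0 = Y[idx(i, j)];
  int state = 0; double best = m0;
  if (x0 > best) { best = x0; state = 1; }
  if (y0 > best) { best = y0; state = 2; }
  double score = best;

  std::vector<int> pa, pb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char tb = tbM[idx(i, j)];
      pa.push_back(i); pb.push_back(j);
      --i; --j;
      state = tb;
    } else if (state == 1) {
      unsigned char tb = tbX[idx(i, j)];
      pa.push_back(i); pb.push_back(0);
      --i;
      state = (tb == 0) ? 0 : 1;
    } else {
      unsigned char tb = tbY[idx(i, j)];
      pa.push_back(0); pb.push_back(j);
      --j;
      state = (tb == 0) ? 0 : 1 + 1;
      if (tb == 0) state = 0; else state = 2;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["pathA"] = IntegerVector(pa.begin(), pa.end()),
                      _["pathB"] = IntegerVector(pb.begin(), pb.end()),
                      _["score"] = score);
}
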