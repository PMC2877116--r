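#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Dynamic-programming kernels shared by sequence-sequence and
// profile-profile alignment.  All kernels take a precomputed cell-score
// matrix C (rows = positions of the first object, columns = positions of
// the second), so the same code serves residue pairs scored by a
// substitution matrix, profile columns scored by expected substitution
// score, and query residues scored against PSSM columns.
//
// Gap model: a gap of length k costs gap_open + k * gap_ext (the first
// gap position pays both the opening and an extension).

static const double NEG_INF = -1e30;

// Global alignment (Needleman-Wunsch) with affine gaps.
// States: M (C-consuming diagonal), X (gap in the second object: consume a
// row, "up"), Y (gap in the first object: consume a column, "left").
// Ties are broken preferring M, then X, then Y, which fixes the traceback.
// Returns the optimal score and the two paths as 1-based position indices
// with 0 marking a gap.
// [[Rcpp::export]]
List nw_core_cpp(NumericMatrix C, double gap_open, double gap_ext) {
  const int n = C.nrow(), m = C.ncol();
  if (n == 0 || m == 0) stop("empty alignment problem");
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // traceback: previous state 0=M,1=X,2=Y; -1 = boundary
  IntegerMatrix tM(n + 1, m + 1), tX(n + 1, m + 1), tY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  tM(0, 0) = tX(0, 0) = tY(0, 0) = -1;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; Y(i, 0) = NEG_INF;
    X(i, 0) = -(gap_open + i * gap_ext);
    tX(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; X(0, j) = NEG_INF;
    Y(0, j) = -(gap_open + j * gap_ext);
    tY(0, j) = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = C(i - 1, j - 1);
      // M from (i-1, j-1), preference M > X > Y on ties
      {
        double a = M(i - 1, j - 1), b = X(i - 1, j - 1), c = Y(i - 1, j - 1);
        int st = 0; double best = a;
        if (b > best) { best = b; st = 1; }
        if (c > best) { best = c; st = 2; }
        M(i, j) = best + s; tM(i, j) = st;
      }
      // X from (i-1, j): open from M or Y, extend from X
      {
        double a = M(i - 1, j) - gap_open - gap_ext;
        double b = X(i - 1, j) - gap_ext;
        double c = Y(i - 1, j) - gap_open - gap_ext;
        int st = 0; double best = a;
        if (b > best) { best = b; st = 1; }
        if (c > best) { best = c; st = 2; }
        X(i, j) = best; tX(i, j) = st;
      }
      // Y from (i, j-1)
      {
        double a = M(i, j - 1) - gap_open - gap_ext;
        double b = X(i, j - 1) - gap_open - gap_ext;
        double c = Y(i, j - 1) - gap_ext;
        int st = 0; double best = a;
        if (b > best) { best = b; st = 1; }
        if (c > best) { best = c; st = 2; }
        Y(i, j) = best; tY(i, j) = st;
      }
    }
  }

  int state = 0;
  double score = M(n, m);
  if (X(n, m) > score) { score = X(n, m); state = 1; }
  if (Y(n, m) > score) { score = Y(n, m); state = 2; }

  std::vector<int> pa, pb;
  pa.reserve(n + m); pb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      pa.push_back(i); pb.push_back(j);
      state = tM(i, j); --i; --j;
    } else if (state == 1) {
      pa.push_back(i); pb.push_back(0);
      state = tX(i, j); --i;
    } else {
      pa.push_back(0); pb.push_back(j);
      state = tY(i, j); --j;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score,
                      _["path_a"] = IntegerVector(pa.begin(), pa.end()),
                      _["path_b"] = IntegerVector(pb.begin(), pb.end()));
}

// Local alignment (Smith-Waterman) with affine gaps on a precomputed
// cell-score matrix; used for scanning a query (rows) against a profile
// (columns).  Returns best score, the 1-based spans on both axes, and the
// number of diagonal (match) cells in the optimal path.
// [[Rcpp::export]]
List sw_align_cpp(NumericMatrix C, double gap_open, double gap_ext) {
  const int n = C.nrow(), m = C.ncol();
  if (n == 0 || m == 0) stop("empty alignment problem");
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix tM(n + 1, m + 1), tX(n + 1, m + 1), tY(n + 1, m + 1);
  for (int j = 0; j <= m; ++j) { M(0, j) = 0; X(0, j) = NEG_INF; Y(0, j) = NEG_INF; }
  for (int i = 0; i <= n; ++i) { M(i, 0) = 0; X(i, 0) = NEG_INF; Y(i, 0) = NEG_INF; }

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = C(i - 1, j - 1);
      {
        double a = M(i - 1, j - 1), b = X(i - 1, j - 1), c = Y(i - 1, j - 1);
        int st = 0; double pv = a;
        if (b > pv) { pv = b; st = 1; }
        if (c > pv) { pv = c; st = 2; }
        if (pv < 0.0) { pv = 0.0; st = -1; }  // fresh local start
        M(i, j) = pv + s; tM(i, j) = st;
      }
      {
        double a = M(i - 1, j) - gap_open - gap_ext;
        double b = X(i - 1, j) - gap_ext;
        int st = 0; double pv = a;
        if (b > pv) { pv = b; st = 1; }
        X(i, j) = pv; tX(i, j) = st;
      }
      {
        double a = M(i, j - 1) - gap_open - gap_ext;
        double c = Y(i, j - 1) - gap_ext;
        int st = 0; double pv = a;
        if (c > pv) { pv = c; st = 2; }
        Y(i, j) = pv; tY(i, j) = st;
      }
      if (M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["p_start"] = NA_INTEGER,
                        _["p_end"] = NA_INTEGER, _["n_match"] = 0);
  }
  // traceback from the best match cell
  int i = bi, j = bj, state = 0, n_match = 0;
  int qs = bi, ps = bj;
  while (i > 0 && j > 0) {
    if (state == 0) {
      ++n_match; qs = i; ps = j;
      int prev = tM(i, j); --i; --j;
      if (prev == -1) break;
      state = prev;
    } else if (state == 1) {
      state = tX(i, j); --i;
    } else {
      state = tY(i, j); --j;
    }
  }
  return List::create(_["score"] = best, _["q_start"] = qs, _["q_end"] = bi,
                      _["p_start"] = ps, _["p_end"] = bj,
                      _["n_match"] = n_match);
}

// Score-only Smith-Waterman in O(m) memory, for null-distribution scoring.
// [[Rcpp::export]]
double sw_score_cpp(NumericMatrix C, double gap_open, double gap_ext) {
  const int n = C.nrow(), m = C.ncol();
  std::vector<double> Mp(m + 1, 0.0), Xp(m + 1, NEG_INF);
  std::vector<double> Mc(m + 1, 0.0), Xc(m + 1, NEG_INF);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    Mc[0] = 0.0; Xc[0] = NEG_INF;
    double Yc = NEG_INF;  // Y(i, j-1) running value
    for (int j = 1; j <= m; ++j) {
      double pv = std::max(std::max(Mp[j - 1], Xp[j - 1]), 0.0);
      // note: Y(i-1, j-1) also feeds M; track it via previous row's Y.
      // For score-only purposes we fold Y into Mp by storing H = max(M,Y)
      // instead; see below.
      Mc[j] = pv + C(i - 1, j - 1);
      Xc[j] = std::max(Mp[j] - gap_open - gap_ext, Xp[j] - gap_ext);
      Yc = std::max(std::max(Mc[j - 1], Xc[j - 1]) - gap_open - gap_ext,
                    Yc - gap_ext);
      // fold Y into the row maximum used by the next diagonal step
      double h = std::max(Mc[j], Yc);
      if (Mc[j] > best) best = Mc[j];
      Mc[j] = h;  // store max(M, Y) as the "H" carried to row i+1
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc);
  }
  return best;
}
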