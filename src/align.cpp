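#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps (Gotoh).
// A gap of length k costs gap_open + k * gap_extend.
// Traceback tie-breaking: prefer diagonal (match state), then up
// (gap in b, i.e. a residue of `a` against a gap), then left.
//
// a, b: 0-based integer encodings into the rows/cols of `submat`.
// Returns list(score, pairs) where pairs is an n x 2 integer matrix of
// 1-based aligned positions (pos_a, pos_b), strictly increasing in both.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".align_global_cpp")]]
List align_global_cpp(IntegerVector a, IntegerVector b,
                      NumericMatrix submat,
                      double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double open_cost = gap_open + gap_extend;  // cost of first gap column

  // State matrices: M ends in a substitution column, X ends with a gap in b
  // (consumes a), Y ends with a gap in a (consumes b).
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG_INF));
  std::vector<std::vector<double>> X(n + 1, std::vector<double>(m + 1, NEG_INF));
  std::vector<std::vector<double>> Y(n + 1, std::vector<double>(m + 1, NEG_INF));

  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i][0] = -(gap_open + i * gap_extend);
  for (int j = 1; j <= m; ++j) Y[0][j] = -(gap_open + j * gap_extend);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = submat(a[i - 1], b[j - 1]);
      const double prev_best =
          std::max(M[i - 1][j - 1], std::max(X[i - 1][j - 1], Y[i - 1][j - 1]));
      M[i][j] = prev_best + s;
      X[i][j] = std::max(M[i - 1][j] - open_cost,
                         std::max(X[i - 1][j] - gap_extend,
                                  Y[i - 1][j] - open_cost));
      Y[i][j] = std::max(M[i][j - 1] - open_cost,
                         std::max(Y[i][j - 1] - gap_extend,
                                  X[i][j - 1] - open_cost));
    }
  }

  const double best =
      std::max(M[n][m], std::max(X[n][m], Y[n][m]));

  // Traceback; state priority M > X (up) > Y (left) on ties.
  std::vector<int> pa, pb;
  int i = n, j = m;
  int state;  // 0 = M, 1 = X, 2 = Y
  if (M[n][m] == best) state = 0;
  else if (X[n][m] == best) state = 1;
  else state = 2;

  while (i > 0 || j > 0) {
    if (state == 0) {
      // arrived via substitution (i-1, j-1) -> (i, j)
      pa.push_back(i);
      pb.push_back(j);
      const double s = submat(a[i - 1], b[j - 1]);
      const double target = M[i][j] - s;
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[i][j] == target) state = 0;
      else if (X[i][j] == target) state = 1;
      else state = 2;
    } else if (state == 1) {
      // gap column consuming a[i-1]
      const double val = X[i][j];
      --i;
      if (M[i][j] - open_cost == val) state = 0;
      else if (X[i][j] - gap_extend == val) state = 1;
      else state = 2;
    } else {
      const double val = Y[i][j];
      --j;
      if (M[i][j] - open_cost == val) state = 0;
      else if (X[i][j] - open_cost == val) state = 1;
      else state = 2;
    }
  }

  const int np = pa.size();
  IntegerMatrix pairs(np, 2);
  for (int k = 0; k < np; ++k) {
    pairs(k, 0) = pa[np - 1 - k];
    pairs(k, 1) = pb[np - 1 - k];
  }
  return List::create(_["score"] = best, _["pairs"] = pairs);
}
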