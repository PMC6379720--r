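#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Global pairwise alignment with affine gap costs (Gotoh). End gaps are
// penalized. A gap of length L costs gap_open + gap_ext * L. Tie-breaking is
// fixed: on equal scores the diagonal (match) state is preferred over a gap
// in the second sequence (up), which is preferred over a gap in the first
// (left), making the traceback deterministic.
//
// a, b: 1-based indices into the scoring matrix rows/cols.
// Returns score and the aligned index vectors (0 = gap).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  const double open_cost = gap_open + gap_ext;

  // state 0 = M (diag), 1 = X (up, gap in b), 2 = Y (left, gap in a)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix pm(n + 1, m + 1), px(n + 1, m + 1), py(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; Y(i, 0) = NEG_INF;
    X(i, 0) = -(gap_open + gap_ext * i);
    px(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; X(0, j) = NEG_INF;
    Y(0, j) = -(gap_open + gap_ext * j);
    py(0, j) = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: consume a[i], b[j]
      double sub = S(a[i - 1] - 1, b[j - 1] - 1);
      double c0 = M(i - 1, j - 1), c1 = X(i - 1, j - 1), c2 = Y(i - 1, j - 1);
      int st = 0; double best = c0;
      if (c1 > best) { best = c1; st = 1; }
      if (c2 > best) { best = c2; st = 2; }
      M(i, j) = sub + best; pm(i, j) = st;

      // X: gap in b, consume a[i] (move up)
      c0 = M(i - 1, j) - open_cost;
      c1 = X(i - 1, j) - gap_ext;
      c2 = Y(i - 1, j) - open_cost;
      st = 0; best = c0;
      if (c1 > best) { best = c1; st = 1; }
      if (c2 > best) { best = c2; st = 2; }
      X(i, j) = best; px(i, j) = st;

      // Y: gap in a, consume b[j] (move left)
      c0 = M(i, j - 1) - open_cost;
      c1 = X(i, j - 1) - open_cost;
      c2 = Y(i, j - 1) - gap_ext;
      st = 0; best = c0;
      if (c1 > best) { best = c1; st = 1; }
      if (c2 > best) { best = c2; st = 2; }
      Y(i, j) = best; py(i, j) = st;
    }
  }

  int state = 0;
  double score = M(n, m);
  if (X(n, m) > score) { score = X(n, m); state = 1; }
  if (Y(n, m) > score) { score = Y(n, m); state = 2; }

  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = pm(i, j);
      ai.push_back(i); bi.push_back(j);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = px(i, j);
      ai.push_back(i); bi.push_back(0);
      --i; state = prev;
    } else {
      int prev = py(i, j);
      ai.push_back(0); bi.push_back(j);
      --j; state = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

  return List::create(_["score"] = score,
                      _["a_idx"] = wrap(ai),
                      _["b_idx"] = wrap(bi));
}
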