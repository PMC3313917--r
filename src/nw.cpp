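#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gap costs, Gotoh
// three-state recursion. A gap run of length L costs open + L * extend.
// Tie-breaking in the traceback is deterministic: diagonal, then up
// (gap in b), then left (gap in a), so identical inputs always give the
// identical alignment string.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix score,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double go = gap_open + gap_extend; // cost of the first gap residue

  // state matrices: 0 = M (diagonal), 1 = X (gap in b, consume a, "up"),
  // 2 = Y (gap in a, consume b, "left")
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // traceback: which predecessor state fed each cell
  IntegerMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);

  M(0, 0) = 0.0;
  X(0, 0) = Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = Y(i, 0) = NEG_INF;
    X(i, 0) = -(gap_open + i * gap_extend);
    tbX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = X(0, j) = NEG_INF;
    Y(0, j) = -(gap_open + j * gap_extend);
    tbY(0, j) = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = score(a[i - 1] - 1, b[j - 1] - 1);
      // M: predecessor preference M > X > Y
      {
        double best = M(i - 1, j - 1); int st = 0;
        if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); st = 1; }
        if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); st = 2; }
        M(i, j) = s + best;
        tbM(i, j) = st;
      }
      // X: gap in b. Extending an X run costs extend only.
      {
        double best = M(i - 1, j) - go; int st = 0;
        if (X(i - 1, j) - gap_extend > best) { best = X(i - 1, j) - gap_extend; st = 1; }
        if (Y(i - 1, j) - go > best) { best = Y(i - 1, j) - go; st = 2; }
        X(i, j) = best;
        tbX(i, j) = st;
      }
      // Y: gap in a.
      {
        double best = M(i, j - 1) - go; int st = 0;
        if (X(i, j - 1) - go > best) { best = X(i, j - 1) - go; st = 1; }
        if (Y(i, j - 1) - gap_extend > best) { best = Y(i, j - 1) - gap_extend; st = 2; }
        Y(i, j) = best;
        tbY(i, j) = st;
      }
    }
  }

  double final_score = M(n, m); int state = 0;
  if (X(n, m) > final_score) { final_score = X(n, m); state = 1; }
  if (Y(n, m) > final_score) { final_score = Y(n, m); state = 2; }

  std::string path; // moves recorded back-to-front: D, U, L
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int prev;
    if (state == 0) {
      prev = tbM(i, j); path.push_back('D'); --i; --j;
    } else if (state == 1) {
      prev = tbX(i, j); path.push_back('U'); --i;
    } else {
      prev = tbY(i, j); path.push_back('L'); --j;
    }
    state = prev;
  }
  std::reverse(path.begin(), path.end());

  IntegerVector ai(path.size()), bi(path.size());
  int pa = 0, pb = 0;
  for (size_t k = 0; k < path.size(); ++k) {
    if (path[k] == 'D') { ai[k] = a[pa++]; bi[k] = b[pb++]; }
    else if (path[k] == 'U') { ai[k] = a[pa++]; bi[k] = 0; }
    else { ai[k] = 0; bi[k] = b[pb++]; }
  }

  return List::create(_["score"] = final_score,
                      _["a_idx"] = ai, _["b_idx"] = bi);
}
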