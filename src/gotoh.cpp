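#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP).
//
// Gap model: a gap run of length L costs gap_open + (L - 1) * gap_extend,
// i.e. the opening column carries the full gap_open penalty. Switching gap
// type (vertical <-> horizontal) opens a new gap.
//
// States: M = diagonal (a[i] vs b[j]); X = gap in b (consumes a, vertical);
// Y = gap in a (consumes b, horizontal).
//
// free_end_a / free_end_b make the terminal overhangs of that sequence free
// (semiglobal recruitment of a short read inside a longer fragment).
//
// Traceback tie-break: diagonal > vertical > horizontal, deterministic.

static const double NEG = -1e18;

// [[Rcpp::export(name = ".gotoh_core")]]
List gotoh_core(std::string a, std::string b,
                double match, double mismatch,
                double gap_open, double gap_extend,
                std::string ambiguous,
                bool free_end_a, bool free_end_b) {
  const int n = (int) a.size(), m = (int) b.size();
  if (n < 1 || m < 1) stop("sequences must be non-empty");
  std::vector<char> amb(256, 0);
  for (size_t k = 0; k < ambiguous.size(); ++k)
    amb[(unsigned char) ambiguous[k]] = 1;
  const size_t W = (size_t) m + 1;

  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    if (free_end_a) X[i * W] = 0.0;
    else X[i * W] = -(gap_open + (i - 1) * gap_extend);
  }
  for (int j = 1; j <= m; ++j) {
    if (free_end_b) Y[j] = 0.0;
    else Y[j] = -(gap_open + (j - 1) * gap_extend);
  }

  for (int i = 1; i <= n; ++i) {
    const size_t r = i * W, p = (i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      char ca = a[i - 1], cb = b[j - 1];
      double s = (ca == cb && !amb[(unsigned char) ca]) ? match : mismatch;
      double dM = M[p + j - 1], dX = X[p + j - 1], dY = Y[p + j - 1];
      double d = dM;
      if (dX > d) d = dX;
      if (dY > d) d = dY;
      M[r + j] = d + s;
      double x = M[p + j] - gap_open;
      if (X[p + j] - gap_extend > x) x = X[p + j] - gap_extend;
      if (Y[p + j] - gap_open > x) x = Y[p + j] - gap_open;
      X[r + j] = x;
      double y = M[r + j - 1] - gap_open;
      if (Y[r + j - 1] - gap_extend > y) y = Y[r + j - 1] - gap_extend;
      if (X[r + j - 1] - gap_open > y) y = X[r + j - 1] - gap_open;
      Y[r + j] = y;
    }
  }

  // End cell: full (n, m) by default; with free trailing overhangs the path
  // may stop early on the corresponding boundary. Strictly-greater updates
  // keep (n, m), then larger j / larger i, preferred — deterministic.
  auto state_at = [&](int i, int j, int &st) {
    const size_t r = (size_t) i * W + j;
    double best = M[r]; st = 0;
    if (X[r] > best) { best = X[r]; st = 1; }
    if (Y[r] > best) { best = Y[r]; st = 2; }
    return best;
  };
  int ei = n, ej = m, est = 0;
  double score = state_at(n, m, est);
  if (free_end_b) {
    for (int j = m - 1; j >= 0; --j) {
      int st; double v = state_at(n, j, st);
      if (v > score) { score = v; ei = n; ej = j; est = st; }
    }
  }
  if (free_end_a) {
    for (int i = n - 1; i >= 0; --i) {
      int st; double v = state_at(i, m, st);
      if (v > score) { score = v; ei = i; ej = m; est = st; }
    }
  }

  std::string ga, gb;
  ga.reserve(n + m); gb.reserve(n + m);
  // trailing free overhangs
  for (int j = m; j > ej; --j) { ga.push_back('-'); gb.push_back(b[j - 1]); }
  for (int i = n; i > ei; --i) { ga.push_back(a[i - 1]); gb.push_back('-'); }

  int i = ei, j = ej, st = est;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (i == 0) {           // leading overhang of b
      ga.push_back('-'); gb.push_back(b[j - 1]); --j; continue;
    }
    if (j == 0) {           // leading overhang of a
      ga.push_back(a[i - 1]); gb.push_back('-'); --i; continue;
    }
    const size_t r = (size_t) i * W, p = (size_t) (i - 1) * W;
    if (st == 0) {
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      char ca = a[i - 1], cb = b[j - 1];
      double s = (ca == cb && !amb[(unsigned char) ca]) ? match : mismatch;
      double v = M[r + j] - s;
      if (std::abs(M[p + j - 1] - v) < eps) st = 0;
      else if (std::abs(X[p + j - 1] - v) < eps) st = 1;
      else st = 2;
      --i; --j;
    } else if (st == 1) {
      ga.push_back(a[i - 1]); gb.push_back('-');
      double v = X[r + j];
      if (std::abs(M[p + j] - gap_open - v) < eps) st = 0;
      else if (std::abs(X[p + j] - gap_extend - v) < eps) st = 1;
      else if (std::abs(Y[p + j] - gap_open - v) < eps) st = 2;
      else st = 1;  // boundary (free leading) run: keep consuming a
      --i;
    } else {
      ga.push_back('-'); gb.push_back(b[j - 1]);
      double v = Y[r + j];
      if (std::abs(M[r + j - 1] - gap_open - v) < eps) st = 0;
      else if (std::abs(X[r + j - 1] - gap_open - v) < eps) st = 1;
      else if (std::abs(Y[r + j - 1] - gap_extend - v) < eps) st = 2;
      else st = 2;  // boundary (free leading) run: keep consuming b
      --j;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());

  return List::create(_["gapped_a"] = ga, _["gapped_b"] = gb,
                      _["score"] = score);
}
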