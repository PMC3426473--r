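#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh), used to place
// ortholog exons in candidate windows of a draft assembly.
//
// Scoring: +match for identical A/C/G/T pairs; -mismatch otherwise, and
// always -mismatch when the target base is N (an assembly gap carries no
// sequence evidence, so N can never support a match). A gap of length L
// costs gap_open + gap_extend * L; gap states may follow any state. The
// empty alignment scores 0.
//
// Traceback is deterministic: the best-scoring cell with the smallest
// (query, target) end position wins, and ties between predecessor states
// prefer diagonal, then up (query base unmatched: deletion from the
// target), then left (extra target base: insertion).

static inline double subst(char q, char t, double match, double mismatch) {
  if (t == 'N' || q == 'N') return -mismatch;
  return (q == t) ? match : -mismatch;
}

// [[Rcpp::export(rng = false)]]
List sw_align_cpp(std::string query, std::string target,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = query.size(), m = target.size();
  if (n == 0) stop("empty query");
  const double NEG = -1e18;
  const double oe = gap_open + gap_extend;
  // state matrices, (n+1) x (m+1); M = diag, X = up (query gap-free,
  // target gapped column: query base deleted), Y = left (target base
  // inserted relative to query)
  std::vector<double> M((n + 1) * (m + 1), 0.0);
  std::vector<double> X((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char qi = query[i - 1];
    double *Mr = &M[(size_t)i * (m + 1)], *Mp = &M[(size_t)(i - 1) * (m + 1)];
    double *Xr = &X[(size_t)i * (m + 1)], *Xp = &X[(size_t)(i - 1) * (m + 1)];
    double *Yr = &Y[(size_t)i * (m + 1)], *Yp = &Y[(size_t)(i - 1) * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      double prev = Mp[j - 1];
      if (Xp[j - 1] > prev) prev = Xp[j - 1];
      if (Yp[j - 1] > prev) prev = Yp[j - 1];
      if (prev < 0.0) prev = 0.0;  // local: fresh start
      const double mm = prev + subst(qi, target[j - 1], match, mismatch);
      Mr[j] = mm;
      double x = Mp[j] - oe;
      if (Xp[j] - gap_extend > x) x = Xp[j] - gap_extend;
      if (Yp[j] - oe > x) x = Yp[j] - oe;
      Xr[j] = x;
      double y = Mr[j - 1] - oe;
      if (Xr[j - 1] - oe > y) y = Xr[j - 1] - oe;
      if (Yr[j - 1] - gap_extend > y) y = Yr[j - 1] - gap_extend;
      Yr[j] = y;
      if (mm > best) { best = mm; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0);
  }
  // traceback from (bi, bj) in state M; a local alignment ends (reading
  // backwards) as soon as its running score reaches 0
  std::string qa, ta;
  int i = bi, j = bj;
  int state = 0;  // 0 = M (diag), 1 = X (up), 2 = Y (left)
  while (i > 0 && j > 0) {
    if (state == 0) {
      qa.push_back(query[i - 1]);
      ta.push_back(target[j - 1]);
      double need = M[at(i, j)] -
        subst(query[i - 1], target[j - 1], match, mismatch);
      --i; --j;
      if (need <= 1e-9) break;  // fresh start: alignment begins here
      const int dg = at(i, j);
      if (std::abs(M[dg] - need) < 1e-9) state = 0;
      else if (std::abs(X[dg] - need) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1) {
      qa.push_back(query[i - 1]);
      ta.push_back('-');
      const int up = at(i - 1, j);
      double cur = X[at(i, j)];
      --i;
      if (std::abs(M[up] - oe - cur) < 1e-9) state = 0;
      else if (std::abs(X[up] - gap_extend - cur) < 1e-9) state = 1;
      else state = 2;
    } else {
      qa.push_back('-');
      ta.push_back(target[j - 1]);
      const int lf = at(i, j - 1);
      double cur = Y[at(i, j)];
      --j;
      if (std::abs(M[lf] - oe - cur) < 1e-9) state = 0;
      else if (std::abs(X[lf] - oe - cur) < 1e-9) state = 1;
      else state = 2;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());
  return List::create(
    _["score"] = best,
    _["qstart"] = i, _["qend"] = bi,
    _["tstart"] = j, _["tend"] = bj,
    _["aligned_query"] = qa, _["aligned_target"] = ta);
}
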