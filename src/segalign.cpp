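#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Banded DP over label positions. b: contig label positions, x: segment
// label positions (both ascending, bp). cum: cumulative expected-observable
// interior label weights for x (length n+1, cum[0] = 0). banned: m x n
// logical, cells that may not be used as matched pairs. fitting forces the
// alignment to pair the first and last labels of both maps.
//
// S[j][q] is the best score of an alignment ending with pair (j, q); a pair
// may start a new alignment with score 0 (any pair for semi-global, only
// (0,0) for fitting). Tie-break among predecessors: smaller (j-i)+(q-p),
// then smaller i.
// [[Rcpp::export]]
List segalign_dp(NumericVector b, NumericVector x, NumericVector cum,
                 double eta, double c, double k, int d, bool fitting,
                 LogicalMatrix banned) {
  const int m = b.size(), n = x.size();
  const double NEG = -1e18;
  if (m == 0 || n == 0) return List::create(_["score"] = NEG);

  NumericMatrix S(m, n);
  IntegerMatrix Pi(m, n), Pp(m, n);
  std::fill(S.begin(), S.end(), NEG);
  std::fill(Pi.begin(), Pi.end(), -1);
  std::fill(Pp.begin(), Pp.end(), -1);

  for (int j = 0; j < m; ++j) {
    for (int q = 0; q < n; ++q) {
      if (banned(j, q)) continue;
      double best = NEG;
      int bi = -1, bp = -1;
      bool can_start = fitting ? (j == 0 && q == 0) : true;
      if (can_start) best = 0.0;
      const int ilo = std::max(0, j - d), plo = std::max(0, q - d);
      for (int i = ilo; i < j; ++i) {
        for (int p = plo; p < q; ++p) {
          if (S(i, p) <= NEG / 2) continue;
          double e_ref = (x[q] - x[p] >= eta) ? (cum[q] - cum[p + 1]) : 0.0;
          double delta = std::pow(std::fabs((b[j] - b[i]) - (x[q] - x[p])), k);
          double sc = S(i, p) + 2.0 * c -
                      (c * (j - i - 1) + c * e_ref + delta);
          bool better = sc > best;
          if (!better && sc == best && bi >= 0) {
            int span_new = (j - i) + (q - p), span_old = (j - bi) + (q - bp);
            better = span_new < span_old || (span_new == span_old && i < bi);
          }
          if (better) { best = sc; bi = i; bp = p; }
        }
      }
      if (best > NEG / 2) { S(j, q) = best; Pi(j, q) = bi; Pp(j, q) = bp; }
    }
  }

  int ej = -1, eq = -1;
  double escore = NEG;
  if (fitting) {
    ej = m - 1; eq = n - 1; escore = S(ej, eq);
    if (escore <= NEG / 2) return List::create(_["score"] = NEG);
  } else {
    for (int j = 0; j < m; ++j)
      for (int q = 0; q < n; ++q)
        if (S(j, q) > escore) { escore = S(j, q); ej = j; eq = q; }
    if (ej < 0) return List::create(_["score"] = NEG);
  }

  std::vector<int> pj, pq;
  int j = ej, q = eq;
  while (j >= 0 && q >= 0) {
    pj.push_back(j); pq.push_back(q);
    int nj = Pi(j, q), nq = Pp(j, q);
    j = nj; q = nq;
  }
  const int K = pj.size();
  IntegerMatrix pairs(K, 2);
  NumericVector steps(std::max(K - 1, 0));
  for (int t = 0; t < K; ++t) {
    pairs(t, 0) = pj[K - 1 - t] + 1;  // 1-based contig index
    pairs(t, 1) = pq[K - 1 - t] + 1;  // 1-based segment index
  }
  for (int t = 0; t + 1 < K; ++t) {
    int i0 = pairs(t, 0) - 1, j1 = pairs(t + 1, 0) - 1;
    int p0 = pairs(t, 1) - 1, q1 = pairs(t + 1, 1) - 1;
    double e_ref = (x[q1] - x[p0] >= eta) ? (cum[q1] - cum[p0 + 1]) : 0.0;
    double delta = std::pow(std::fabs((b[j1] - b[i0]) - (x[q1] - x[p0])), k);
    steps[t] = 2.0 * c - (c * (j1 - i0 - 1) + c * e_ref + delta);
  }
  return List::create(_["score"] = escore, _["pairs"] = pairs,
                      _["steps"] = steps);
}
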