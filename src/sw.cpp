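#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Smith-Waterman local alignment score with affine gaps, score only.
//
// a, b:   0-based integer residue codes indexing rows/cols of smat
// smat:   symmetric substitution matrix (integer)
// gap_open, gap_extend: negative; a gap of length k costs gap_open + k*gap_extend
//
// Classical Gotoh recurrences with the local-alignment zero floor; the
// empty alignment scores 0, so the result is always >= 0.
// [[Rcpp::export(name = ".sw_score_int")]]
int sw_score_int(IntegerVector a, IntegerVector b, IntegerMatrix smat,
                 int gap_open, int gap_extend) {
  int n = a.size(), m = b.size(), K = smat.nrow();
  std::vector<int> H(m + 1, 0), E(m + 1, INT_MIN / 4);
  int best = 0;
  int go = gap_open + gap_extend, ge = gap_extend;
  const int *S = smat.begin();
  for (int i = 1; i <= n; ++i) {
    int diag = 0;        // H[i-1][j-1]
    int F = INT_MIN / 4; // gap in b (vertical)
    const int *Srow = S + (size_t)a[i - 1];
    int Hprev = 0;       // H[i][0]
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(H[j] + go, E[j] + ge); // H[j] still holds row i-1
      F = std::max(Hprev + go, F + ge);
      int h = diag + Srow[(size_t)b[j - 1] * K];
      if (E[j] > h) h = E[j];
      if (F > h) h = F;
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      Hprev = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Scores of one subject against many queries (avoids R-level call overhead).
// [[Rcpp::export(name = ".sw_score_many")]]
IntegerVector sw_score_many(List queries, IntegerVector subject,
                            IntegerMatrix smat, int gap_open, int gap_extend) {
  int nq = queries.size();
  IntegerVector out(nq);
  for (int q = 0; q < nq; ++q) {
    IntegerVector a = queries[q];
    out[q] = sw_score_int(a, subject, smat, gap_open, gap_extend);
  }
  return out;
}
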