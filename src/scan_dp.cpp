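#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Local alignment of a position-specific scoring profile against a protein
// sequence, Smith-Waterman style with affine gaps. `emissions` is an L x A
// score matrix (bits); `seq` holds 0-based column indices into it; excluded
// sequence positions cannot take part in any alignment (used for greedy
// non-overlapping multi-hit extraction). A local alignment starts and ends
// with a profile column aligned to a residue; deleted profile columns score
// gap_open/gap_extend, as do inserted sequence residues.
// [[Rcpp::export]]
List scan_dp(NumericMatrix emissions, IntegerVector seq, double gap_open,
             double gap_extend, LogicalVector exclude) {
  const int L = emissions.nrow();
  const int n = seq.size();
  const double NEG = -1e9;
  const int W = n + 1;
  std::vector<double> M((L + 1) * W, NEG), Ix((L + 1) * W, NEG),
      Iy((L + 1) * W, NEG);
  // predecessor state: 0 = local start, 1 = M, 2 = Ix, 3 = Iy
  std::vector<signed char> tM((L + 1) * W, 0), tIx((L + 1) * W, 0),
      tIy((L + 1) * W, 0);
  const int w = W;
  double best = 0.0;
  int bi = -1, bj = -1;
  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int idx = i * w + j;
      const int dg = (i - 1) * w + (j - 1);
      const int lf = i * w + (j - 1);
      const int up = (i - 1) * w + j;
      if (!exclude[j - 1]) {
        double m = 0.0;
        signed char tr = 0;
        if (M[dg] > m) { m = M[dg]; tr = 1; }
        if (Ix[dg] > m) { m = Ix[dg]; tr = 2; }
        if (Iy[dg] > m) { m = Iy[dg]; tr = 3; }
        M[idx] = m + emissions(i - 1, seq[j - 1]);
        tM[idx] = tr;
        const double oM = M[lf] + gap_open;
        const double oIx = Ix[lf] + gap_extend;
        if (oM >= oIx) { Ix[idx] = oM; tIx[idx] = 1; }
        else           { Ix[idx] = oIx; tIx[idx] = 2; }
      }
      const double uM = M[up] + gap_open;
      const double uIy = Iy[up] + gap_extend;
      if (uM >= uIy) { Iy[idx] = uM; tIy[idx] = 1; }
      else           { Iy[idx] = uIy; tIy[idx] = 3; }
      if (M[idx] > best) { best = M[idx]; bi = i; bj = j; }
    }
  }
  if (bi < 0 || best <= 0.0) {
    return List::create(_["score"] = 0.0, _["start"] = NA_INTEGER,
                        _["end"] = NA_INTEGER,
                        _["match_pos"] = IntegerVector(L, 0));
  }
  // match_pos: per profile column, the 1-based aligned sequence position,
  // -1 for a deleted column inside the alignment, 0 outside the alignment
  IntegerVector match_pos(L, 0);
  int i = bi, j = bj, state = 1, start = bj;
  while (true) {
    if (state == 1) {
      match_pos[i - 1] = j;
      start = j;
      const signed char tr = tM[i * w + j];
      --i; --j;
      if (tr == 0) break;
      state = tr;
    } else if (state == 2) {
      const signed char tr = tIx[i * w + j];
      --j;
      state = tr;
    } else {
      match_pos[i - 1] = -1;
      const signed char tr = tIy[i * w + j];
      --i;
      state = tr;
    }
  }
  return List::create(_["score"] = best, _["start"] = start,
                      _["end"] = bj, _["match_pos"] = match_pos);
}
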