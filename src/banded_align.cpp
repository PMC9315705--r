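// Banded global pairwise alignment (Gotoh affine-gap DP) for near-identical
// plastome sequences. The band covers diagonals j - i in
// [min(0, m-n) - band, max(0, m-n) + band], so the end cell is always inside
// the band; a best path that touches the band edge is flagged so the caller
// can refuse the alignment instead of silently truncating the optimum.
//
// Gap convention matches Biostrings::pairwiseAlignment: the first base of a
// gap costs gap_open + gap_ext, each further base gap_ext.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const int NEG = -1000000000;

// traceback codes packed per cell: 2 bits each for M, X, Y
// predecessor state: 0 = M, 1 = X, 2 = Y, 3 = unset/origin
static inline uint8_t pack(int pm, int px, int py) {
  return (uint8_t)((pm & 3) | ((px & 3) << 2) | ((py & 3) << 4));
}

// [[Rcpp::export]]
List cpp_banded_align(std::string ref, std::string qry, int band,
                      int match, int mismatch, int gap_open, int gap_ext) {
  const int n = (int)ref.size();
  const int m = (int)qry.size();
  const int lo = std::min(0, m - n) - band;
  const int hi = std::max(0, m - n) + band;
  const int W = hi - lo + 1;
  const int go = gap_open + gap_ext;   // cost of the first gap base

  std::vector<int> Mp(W, NEG), Xp(W, NEG), Yp(W, NEG);
  std::vector<int> Mc(W), Xc(W), Yc(W);
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 0);

  // row 0: only insertions (consume qry)
  {
    int jlo = std::max(0, lo), jhi = std::min(m, hi);
    for (int j = jlo; j <= jhi; ++j) {
      int k = j - lo;
      if (j == 0) { Mp[k] = 0; }
      else {
        int fromM = (j - 1 - lo >= 0 && Mp[j - 1 - lo] > NEG) ? Mp[j - 1 - lo] + go : NEG;
        int fromY = (j - 1 - lo >= 0 && Yp[j - 1 - lo] > NEG) ? Yp[j - 1 - lo] + gap_ext : NEG;
        if (fromM >= fromY) { Yp[k] = fromM; tb[k] |= pack(3, 3, 0); }
        else { Yp[k] = fromY; tb[k] |= pack(3, 3, 2); }
      }
    }
  }

  for (int i = 1; i <= n; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Xc.begin(), Xc.end(), NEG);
    std::fill(Yc.begin(), Yc.end(), NEG);
    const int jlo = std::max(0, i + lo), jhi = std::min(m, i + hi);
    uint8_t *tbrow = &tb[(size_t)i * W];
    for (int j = jlo; j <= jhi; ++j) {
      const int k = j - i - lo;          // band index: same k refers to the
                                         // same diagonal in the previous row
      int pm = 3, px = 3, py = 3;
      // M: diagonal predecessor is (i-1, j-1) -> same band index k
      if (j >= 1) {
        int s = (ref[i - 1] == qry[j - 1] && ref[i - 1] != 'N') ? match : mismatch;
        int bm = Mp[k], bx = Xp[k], by = Yp[k];
        int best = bm; pm = 0;
        if (bx > best) { best = bx; pm = 1; }
        if (by > best) { best = by; pm = 2; }
        if (best > NEG) Mc[k] = best + s; else pm = 3;
      }
      // X: consume ref base, predecessor (i-1, j) -> band index k+1
      if (k + 1 < W) {
        int fm = (Mp[k + 1] > NEG) ? Mp[k + 1] + go : NEG;
        int fx = (Xp[k + 1] > NEG) ? Xp[k + 1] + gap_ext : NEG;
        int fy = (Yp[k + 1] > NEG) ? Yp[k + 1] + go : NEG;
        int best = fm; px = 0;
        if (fx > best) { best = fx; px = 1; }
        if (fy > best) { best = fy; px = 2; }
        if (best > NEG) Xc[k] = best; else px = 3;
      }
      // Y: consume qry base, predecessor (i, j-1) -> band index k-1
      if (k - 1 >= 0 && j >= 1) {
        int fm = (Mc[k - 1] > NEG) ? Mc[k - 1] + go : NEG;
        int fx = (Xc[k - 1] > NEG) ? Xc[k - 1] + go : NEG;
        int fy = (Yc[k - 1] > NEG) ? Yc[k - 1] + gap_ext : NEG;
        int best = fm; py = 0;
        if (fx > best) { best = fx; py = 1; }
        if (fy > best) { best = fy; py = 2; }
        if (best > NEG) Yc[k] = best; else py = 3;
      }
      tbrow[k] = pack(pm, px, py);
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  const int kend = m - n - lo;
  int score = Mp[kend], state = 0;
  if (Xp[kend] > score) { score = Xp[kend]; state = 1; }
  if (Yp[kend] > score) { score = Yp[kend]; state = 2; }
  if (score <= NEG)
    return List::create(_["ok"] = false);

  // traceback
  std::string ra, qa;
  ra.reserve(n + band); qa.reserve(m + band);
  int i = n, j = m;
  bool edge = false;
  long steps = 0, max_steps = (long)n + m + 10;
  while (i > 0 || j > 0) {
    if (++steps > max_steps) return List::create(_["ok"] = false);
    const int k = j - i - lo;
    if ((k == 0 || k == W - 1) && j > 0 && j < m) edge = true;
    uint8_t code = tb[(size_t)i * W + k];
    if (state == 0) {
      ra.push_back(ref[i - 1]); qa.push_back(qry[j - 1]);
      state = code & 3; --i; --j;
      if (state == 3) break;
    } else if (state == 1) {
      ra.push_back(ref[i - 1]); qa.push_back('-');
      state = (code >> 2) & 3; --i;
    } else {
      ra.push_back('-'); qa.push_back(qry[j - 1]);
      state = (code >> 4) & 3; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(qa.begin(), qa.end());
  return List::create(_["ok"] = true, _["score"] = score,
                      _["ref"] = ra, _["qry"] = qa,
                      _["edge"] = edge);
}
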