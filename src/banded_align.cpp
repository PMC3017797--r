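#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Banded global alignment with affine gaps.
//
// Scoring convention: a gap of length L costs gap_open + L * gap_ext
// (opening does not include the first extension), matching the
// Needleman-Wunsch/Gotoh variant used by Biostrings::pairwiseAlignment.
//
// The band is defined on the diagonal d = j - i: cells with
// dmin - band <= d <= dmax + band are computed, where dmin/dmax bracket
// the corner-to-corner diagonal drift. band_hit is set when the optimal
// path touches the band boundary, so callers can retry with a wider band.

static const int NEG_INF = std::numeric_limits<int>::min() / 4;

// [[Rcpp::export]]
List align_global_cpp(std::string a, std::string b,
                      int match, int mismatch,
                      int gap_open, int gap_ext,
                      int band) {
  const int na = (int)a.size(), nb = (int)b.size();
  if (na == 0 || nb == 0) {
    // pure gap alignment: one side is all gaps, the other unchanged
    int L = na + nb;
    int sc = (L > 0) ? -(gap_open + gap_ext * L) : 0;
    return List::create(_["score"] = sc,
                        _["aligned_a"] = (na ? a : std::string(nb, '-')),
                        _["aligned_b"] = (nb ? b : std::string(na, '-')),
                        _["band_hit"] = false);
  }
  const int dmin = std::min(0, nb - na), dmax = std::max(0, nb - na);
  const int lo_d = dmin - band, hi_d = dmax + band;
  const int W = hi_d - lo_d + 1;  // band width in diagonals

  // DP matrices stored as (na+1) rows x W columns; column w <-> d = lo_d + w
  std::vector<int> M((size_t)(na + 1) * W, NEG_INF);
  std::vector<int> X((size_t)(na + 1) * W, NEG_INF);  // gap in b (consumes a)
  std::vector<int> Y((size_t)(na + 1) * W, NEG_INF);  // gap in a (consumes b)
  // traceback: 2 bits per matrix packed in a byte per cell
  std::vector<unsigned char> TB((size_t)(na + 1) * W, 0);

  auto idx = [W](int i, int w) { return (size_t)i * W + w; };

  // init (i=0 row: j = d since d = j - 0)
  for (int w = 0; w < W; ++w) {
    int j = lo_d + w;
    if (j < 0 || j > nb) continue;
    if (j == 0) { M[idx(0, w)] = 0; }
    else { Y[idx(0, w)] = -(gap_open + gap_ext * j); }
  }
  for (int i = 1; i <= na; ++i) {
    int w0 = 0 - i - lo_d;  // column for j = 0
    if (w0 >= 0 && w0 < W) X[idx(i, w0)] = -(gap_open + gap_ext * i);
    for (int w = 0; w < W; ++w) {
      int j = i + lo_d + w;
      if (j < 1 || j > nb) continue;
      size_t c = idx(i, w);
      unsigned char tb = 0;
      // M: diagonal move from (i-1, j-1), same w in this parameterisation
      {
        int prev = std::max(M[idx(i - 1, w)],
                            std::max(X[idx(i - 1, w)], Y[idx(i - 1, w)]));
        if (prev > NEG_INF) {
          int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
          M[c] = prev + s;
          int pm = M[idx(i - 1, w)], px = X[idx(i - 1, w)];
          tb |= (prev == pm) ? 0 : (prev == px ? 1 : 2);
        }
      }
      // X: gap in b, from (i-1, j) -> w+1
      if (w + 1 < W) {
        size_t p = idx(i - 1, w + 1);
        int openX = std::max(M[p], Y[p]);
        int ext = X[p];
        int vo = (openX > NEG_INF) ? openX - gap_open - gap_ext : NEG_INF;
        int ve = (ext > NEG_INF) ? ext - gap_ext : NEG_INF;
        if (vo >= ve) { X[c] = vo; }
        else { X[c] = ve; tb |= 4; }
      }
      // Y: gap in a, from (i, j-1) -> w-1
      if (w - 1 >= 0) {
        size_t p = idx(i, w - 1);
        int openY = std::max(M[p], X[p]);
        int ext = Y[p];
        int vo = (openY > NEG_INF) ? openY - gap_open - gap_ext : NEG_INF;
        int ve = (ext > NEG_INF) ? ext - gap_ext : NEG_INF;
        if (vo >= ve) { Y[c] = vo; }
        else { Y[c] = ve; tb |= 8; }
      }
      TB[c] = tb;
    }
  }

  int wend = nb - na - lo_d;
  if (wend < 0 || wend >= W) stop("band does not contain alignment endpoint");
  size_t e = idx(na, wend);
  int best = std::max(M[e], std::max(X[e], Y[e]));
  if (best <= NEG_INF) stop("band too narrow: no path");

  // traceback
  std::string ra, rb;
  ra.reserve(na + nb); rb.reserve(na + nb);
  int i = na, w = wend;
  int state = (best == M[e]) ? 0 : (best == X[e] ? 1 : 2);
  bool band_hit = false;
  while (true) {
    int j = i + lo_d + w;
    if (i == 0 && j == 0) break;
    if (w == 0 || w == W - 1) band_hit = true;
    unsigned char tb = TB[idx(i, w)];
    if (state == 0) {
      if (i == 0 || j == 0) { state = (i == 0) ? 2 : 1; continue; }
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      int prev = tb & 3;
      --i;  // w unchanged (diagonal)
      state = prev;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      bool ext = (tb & 4) != 0;
      --i; ++w;
      if (!ext) {
        size_t p = idx(i, w);
        state = (M[p] >= Y[p]) ? 0 : 2;
      }
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      bool ext = (tb & 8) != 0;
      --w;
      if (!ext) {
        size_t p = idx(i, w);
        state = (M[p] >= X[p]) ? 0 : 1;
      }
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = best,
                      _["aligned_a"] = ra,
                      _["aligned_b"] = rb,
                      _["band_hit"] = band_hit);
}
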