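#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Global pairwise alignment (Gotoh affine-gap Needleman-Wunsch).
// Scoring: match +1, mismatch -1; the first column of a gap scores
// gap_open, each further column gap_extend. Ties are broken
// deterministically: diagonal preferred, then the gap-in-b ("up") state,
// then gap-in-a. State matrices: M (diagonal), X (gap in b: consume a),
// Y (gap in a: consume b). Scores are kept in two rolling rows; the
// traceback is one byte per cell (2 bits per state matrix).

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match = 1.0, double mismatch = -1.0,
                  double gap_open = -2.0, double gap_extend = -0.5) {
  const size_t m = a.size(), n = b.size();
  const size_t W = n + 1;

  std::vector<double> Mp(W), Xp(W), Yp(W), Mc(W), Xc(W), Yc(W);
  // packed traceback: bits 0-1 predecessor of M, 2-3 of X, 4-5 of Y
  std::vector<uint8_t> tb((m + 1) * W, 0);

  Mp[0] = 0.0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
  for (size_t j = 1; j <= n; ++j) {
    Mp[j] = NEG_INF; Xp[j] = NEG_INF;
    Yp[j] = gap_open + gap_extend * (double)(j - 1);
    tb[j] |= (uint8_t)((j == 1 ? 0 : 2) << 4);
  }

  for (size_t i = 1; i <= m; ++i) {
    const char ca = a[i - 1];
    uint8_t* tr = &tb[i * W];
    Mc[0] = NEG_INF; Yc[0] = NEG_INF;
    Xc[0] = gap_open + gap_extend * (double)(i - 1);
    tr[0] = (uint8_t)((i == 1 ? 0 : 1) << 2);
    for (size_t j = 1; j <= n; ++j) {
      const double s = (ca == b[j - 1]) ? match : mismatch;
      uint8_t cell = 0;
      // M: diagonal step from (i-1, j-1); ties prefer M, then X, then Y
      {
        double best = Mp[j - 1]; uint8_t st = 0;
        if (Xp[j - 1] > best) { best = Xp[j - 1]; st = 1; }
        if (Yp[j - 1] > best) { best = Yp[j - 1]; st = 2; }
        Mc[j] = best + s; cell |= st;
      }
      // X: gap in b (consume a[i]) from (i-1, j)
      {
        double fromM = Mp[j] + gap_open;
        double fromX = Xp[j] + gap_extend;
        if (fromM >= fromX) { Xc[j] = fromM; }
        else               { Xc[j] = fromX; cell |= (1 << 2); }
      }
      // Y: gap in a (consume b[j]) from (i, j-1)
      {
        double fromM = Mc[j - 1] + gap_open;
        double fromY = Yc[j - 1] + gap_extend;
        if (fromM >= fromY) { Yc[j] = fromM; }
        else               { Yc[j] = fromY; cell |= (2 << 4); }
      }
      tr[j] = cell;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  // final state: prefer M, then X ("up"), then Y on ties
  uint8_t state = 0;
  double best = Mp[n];
  if (Xp[n] > best) { best = Xp[n]; state = 1; }
  if (Yp[n] > best) { best = Yp[n]; state = 2; }

  std::string out_a, out_b;
  out_a.reserve(m + n); out_b.reserve(m + n);
  size_t i = m, j = n;
  while (i > 0 || j > 0) {
    const uint8_t cell = tb[i * W + j];
    if (state == 0) {
      out_a.push_back(a[i - 1]); out_b.push_back(b[j - 1]);
      --i; --j; state = cell & 3;
    } else if (state == 1) {
      out_a.push_back(a[i - 1]); out_b.push_back('-');
      --i; state = (cell >> 2) & 3;
    } else {
      out_a.push_back('-'); out_b.push_back(b[j - 1]);
      --j; state = (cell >> 4) & 3;
    }
  }
  std::reverse(out_a.begin(), out_a.end());
  std::reverse(out_b.begin(), out_b.end());

  return List::create(_["aligned_a"] = out_a, _["aligned_b"] = out_b,
                      _["score"] = best);
}
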