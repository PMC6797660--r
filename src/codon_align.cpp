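// Codon-aware global alignment with free end gaps.
//
// Needleman-Wunsch variant for comparing coding sequences of a gene
// family: affine gaps carry an extra frameshift penalty when an internal
// gap run closes at a length that is not a multiple of 3, so in-frame
// length variation (poly-Q and repeat-count differences) is represented as
// 3-periodic gaps and the reading-frame register of the reference is
// preserved across them. Terminal gap runs are free on both sequences
// (truncated genes align with clean terminal overhangs). Gap state tracks
// run length mod 3 (7 states total); adjacent opposite-sense gaps are
// disallowed; ties break in a fixed state order so the alignment is
// deterministic.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static const double NEG = -1e18;

// state codes: 0 = M, 1..3 = D (gap in query) mod 1,2,0; 4..6 = I (gap in
// reference) mod 1,2,0
enum { SM = 0, SD1 = 1, SD2 = 2, SD0 = 3, SI1 = 4, SI2 = 5, SI0 = 6 };

struct TB { signed char state[7]; }; // predecessor state per state, -1 = start

// [[Rcpp::export(name = ".codon_align_cpp")]]
List codon_align_cpp(std::string q, std::string r, double match,
                     double mismatch, double gap_open, double gap_extend,
                     double frameshift, int band) {
  const int n = (int)q.size(), m = (int)r.size();
  // band <= 0 disables banding; otherwise cells with a diagonal offset
  // outside [min(0, m-n) - band, max(0, m-n) + band] stay unreachable
  const int blo = (band > 0) ? std::min(0, m - n) - band : -2000000000;
  const int bhi = (band > 0) ? std::max(0, m - n) + band : 2000000000;
  auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };
  std::vector<std::array<double, 7>> dp((size_t)(n + 1) * (m + 1));
  std::vector<TB> tb((size_t)(n + 1) * (m + 1));
  for (auto &c : dp) c.fill(NEG);
  // free leading gaps: any (i,0) or (0,j) is a valid start point
  for (int j = 0; j <= m; ++j) dp[idx(0, j)][SM] = 0.0;
  for (int i = 0; i <= n; ++i) dp[idx(i, 0)][SM] = 0.0;
  for (int i = 0; i <= n; ++i)
    for (int s = 0; s < 7; ++s) tb[idx(i, 0)].state[s] = -1;
  for (int j = 0; j <= m; ++j)
    for (int s = 0; s < 7; ++s) tb[idx(0, j)].state[s] = -1;

  // closing penalty when leaving a gap state whose run length mod 3 != 0
  auto close_pen = [frameshift](int s) {
    return (s == SD1 || s == SD2 || s == SI1 || s == SI2) ? frameshift : 0.0;
  };

  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, (band > 0) ? i + blo : 1);
    int jhi = std::min(m, (band > 0) ? i + bhi : m);
    for (int j = jlo; j <= jhi; ++j) {
      std::array<double, 7> &cur = dp[idx(i, j)];
      TB &t = tb[idx(i, j)];
      const std::array<double, 7> &diag = dp[idx(i - 1, j - 1)];
      const std::array<double, 7> &up = dp[idx(i - 1, j)];   // consumes query
      const std::array<double, 7> &left = dp[idx(i, j - 1)]; // consumes ref
      double s_sub = (q[i - 1] == r[j - 1]) ? match : mismatch;
      // M: align q[i-1] with r[j-1]; charge close penalty on gap exits
      {
        double best = NEG; int bs = -2;
        for (int s = 0; s < 7; ++s) {
          if (diag[s] <= NEG / 2) continue;
          double v = diag[s] + s_sub + (s == SM ? 0.0 : close_pen(s));
          if (v > best + 1e-12) { best = v; bs = s; }
        }
        // fresh start from a boundary cell counts as coming from SM there
        cur[SM] = best; t.state[SM] = (signed char)bs;
      }
      // D states: gap in query (ref base j-1 unmatched)
      {
        // open from M
        double from_open = (left[SM] > NEG / 2) ?
          left[SM] + gap_open + gap_extend : NEG;
        // extend: mod counter advances 1 -> 2 -> 0 -> 1
        double e1 = (left[SD0] > NEG / 2) ? left[SD0] + gap_extend : NEG;
        double e2 = (left[SD1] > NEG / 2) ? left[SD1] + gap_extend : NEG;
        double e0 = (left[SD2] > NEG / 2) ? left[SD2] + gap_extend : NEG;
        cur[SD1] = std::max(from_open, e1);
        t.state[SD1] = (from_open >= e1) ? SM : SD0;
        cur[SD2] = e2; t.state[SD2] = SD1;
        cur[SD0] = e0; t.state[SD0] = SD2;
      }
      // I states: gap in reference (query base i-1 unmatched)
      {
        double from_open = (up[SM] > NEG / 2) ?
          up[SM] + gap_open + gap_extend : NEG;
        double e1 = (up[SI0] > NEG / 2) ? up[SI0] + gap_extend : NEG;
        double e2 = (up[SI1] > NEG / 2) ? up[SI1] + gap_extend : NEG;
        double e0 = (up[SI2] > NEG / 2) ? up[SI2] + gap_extend : NEG;
        cur[SI1] = std::max(from_open, e1);
        t.state[SI1] = (from_open >= e1) ? SM : SI0;
        cur[SI2] = e2; t.state[SI2] = SI1;
        cur[SI0] = e0; t.state[SI0] = SI2;
      }
    }
  }
  // free trailing gaps: best M over last row / last column
  double best = NEG; int bi = n, bj = m;
  for (int j = m; j >= 0; --j) {
    if (dp[idx(n, j)][SM] > best + 1e-12) { best = dp[idx(n, j)][SM]; bi = n; bj = j; }
  }
  for (int i = n; i >= 0; --i) {
    if (dp[idx(i, m)][SM] > best + 1e-12) { best = dp[idx(i, m)][SM]; bi = i; bj = m; }
  }
  if (best <= NEG / 2) { best = 0.0; bi = 0; bj = 0; } // no aligned pair
  // traceback
  std::string qa, ra;
  // trailing free gaps
  for (int i = n; i > bi; --i) { qa.push_back(q[i - 1]); ra.push_back('-'); }
  for (int j = m; j > bj; --j) { qa.push_back('-'); ra.push_back(r[j - 1]); }
  int i = bi, j = bj, s = SM;
  while (i > 0 && j > 0) {
    signed char prev = tb[idx(i, j)].state[s];
    if (s == SM) {
      if (prev == -2) break; // hit an unreachable cell (should not happen)
      qa.push_back(q[i - 1]); ra.push_back(r[j - 1]);
      --i; --j;
      if (prev == -1) break; // started at boundary
      s = prev;
    } else if (s == SD1 || s == SD2 || s == SD0) {
      qa.push_back('-'); ra.push_back(r[j - 1]);
      --j; s = prev;
    } else {
      qa.push_back(q[i - 1]); ra.push_back('-');
      --i; s = prev;
    }
  }
  // leading free gaps
  for (; i > 0; --i) { qa.push_back(q[i - 1]); ra.push_back('-'); }
  for (; j > 0; --j) { qa.push_back('-'); ra.push_back(r[j - 1]); }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ra.begin(), ra.end());
  return List::create(_["query"] = qa, _["reference"] = ra,
                      _["score"] = best);
}

// score-only variant with rolling rows (for reference selection)
// [[Rcpp::export(name = ".codon_align_score_cpp")]]
double codon_align_score_cpp(std::string q, std::string r, double match,
                             double mismatch, double gap_open,
                             double gap_extend, double frameshift) {
  const int n = (int)q.size(), m = (int)r.size();
  auto close_pen = [frameshift](int s) {
    return (s == SD1 || s == SD2 || s == SI1 || s == SI2) ? frameshift : 0.0;
  };
  std::vector<std::array<double, 7>> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) { prev[j].fill(NEG); prev[j][SM] = 0.0; }
  double best = prev[m][SM];
  // band: free end gaps absorb the length difference; internal drift
  // (poly-Q variation, small indels) stays well inside the margin
  const int margin = 150;
  const int blo = std::min(0, m - n) - margin;
  const int bhi = std::max(0, m - n) + margin;
  for (int i = 1; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) cur[j].fill(NEG);
    cur[0][SM] = 0.0;
    int jlo = std::max(1, i + blo), jhi = std::min(m, i + bhi);
    for (int j = jlo; j <= jhi; ++j) {
      double s_sub = (q[i - 1] == r[j - 1]) ? match : mismatch;
      double bm = NEG;
      for (int s = 0; s < 7; ++s) {
        if (prev[j - 1][s] <= NEG / 2) continue;
        double v = prev[j - 1][s] + s_sub + (s == SM ? 0.0 : close_pen(s));
        if (v > bm) bm = v;
      }
      cur[j][SM] = bm;
      double fo = (cur[j - 1][SM] > NEG / 2) ?
        cur[j - 1][SM] + gap_open + gap_extend : NEG;
      cur[j][SD1] = std::max(fo, (cur[j - 1][SD0] > NEG / 2) ?
                                   cur[j - 1][SD0] + gap_extend : NEG);
      cur[j][SD2] = (cur[j - 1][SD1] > NEG / 2) ?
        cur[j - 1][SD1] + gap_extend : NEG;
      cur[j][SD0] = (cur[j - 1][SD2] > NEG / 2) ?
        cur[j - 1][SD2] + gap_extend : NEG;
      double fo2 = (prev[j][SM] > NEG / 2) ?
        prev[j][SM] + gap_open + gap_extend : NEG;
      cur[j][SI1] = std::max(fo2, (prev[j][SI0] > NEG / 2) ?
                                    prev[j][SI0] + gap_extend : NEG);
      cur[j][SI2] = (prev[j][SI1] > NEG / 2) ?
        prev[j][SI1] + gap_extend : NEG;
      cur[j][SI0] = (prev[j][SI2] > NEG / 2) ?
        prev[j][SI2] + gap_extend : NEG;
    }
    if (cur[m][SM] > best) best = cur[m][SM];
    std::swap(prev, cur);
  }
  for (int j = 0; j <= m; ++j)
    if (prev[j][SM] > best) best = prev[j][SM];
  return best <= NEG / 2 ? 0.0 : best;
}
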