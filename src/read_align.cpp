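// Seed-and-extend read-to-gene alignment with explicit mismatch/indel
// costs. A k-mer index over the gene set proposes candidate (gene, offset)
// placements; each candidate is rescored by a banded dynamic program that
// is global in the read and anchored in the gene, minimising
// mismatch_cost * mismatches + indel_cost * indels. Read bases running
// past a gene end are soft-clipped for free and excluded from both the
// identity and the aligned-length fraction; identity is
// matches / alignment columns, length fraction aligned read bases / read
// length.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static const int BAND = 4;
static const double INF_COST = 1e18;

// banded alignment of the whole read against gene[g0, g1) where the
// expected start is gstart; clipping allowed only off the gene's ends
static bool banded_align(const std::string &read, const std::string &gene,
                         int gstart, double mismatch_cost, double indel_cost,
                         int max_clip, double &cost, double &identity,
                         double &length_fraction) {
  const int L = (int)read.size();
  const int G = (int)gene.size();
  int g0 = std::max(0, gstart - BAND);
  int g1 = std::min(G, gstart + L + BAND);
  int W = g1 - g0;
  if (W <= 0) return false;
  bool at_start = (g0 == 0), at_end = (g1 == G);
  int offset = gstart - g0; // expected diagonal
  std::vector<std::vector<double>> dp(L + 1, std::vector<double>(W + 1, INF_COST));
  for (int j = 0; j <= W; ++j) dp[0][j] = 0.0; // free leading gene bases
  for (int i = 1; i <= L; ++i) {
    int jlo = std::max(0, i + offset - BAND);
    int jhi = std::min(W, i + offset + BAND);
    if (at_start) jlo = 0;          // allow prefix clipping column
    if (at_end && W <= i + offset + BAND) jhi = W;
    for (int j = jlo; j <= jhi; ++j) {
      if (j != 0 && j != W && (j < i + offset - BAND || j > i + offset + BAND))
        continue;
      double best = INF_COST;
      if (j > 0 && dp[i - 1][j - 1] < INF_COST) {
        best = std::min(best, dp[i - 1][j - 1] +
          (read[i - 1] == gene[g0 + j - 1] ? 0.0 : mismatch_cost));
      }
      if (dp[i - 1][j] < INF_COST) { // read base not matched to gene
        double vcost = indel_cost;
        // soft clips: at most max_clip prefix bases before the gene start,
        // at most max_clip suffix bases past the gene end
        if ((j == 0 && at_start && i <= max_clip) ||
            (j == W && at_end && i >= (int)read.size() - max_clip + 1))
          vcost = 0.0;
        best = std::min(best, dp[i - 1][j] + vcost);
      }
      if (j > 0 && dp[i][j - 1] < INF_COST) // extra gene base (insertion)
        best = std::min(best, dp[i][j - 1] + indel_cost);
      dp[i][j] = best;
    }
  }
  int jbest = -1;
  double cbest = INF_COST;
  for (int j = 0; j <= W; ++j) {
    if (dp[L][j] < cbest) { cbest = dp[L][j]; jbest = j; }
  }
  if (jbest < 0 || cbest >= INF_COST) return false;
  // traceback to count matches / columns / aligned read bases
  int i = L, j = jbest;
  long matches = 0, columns = 0, read_aligned = 0;
  while (i > 0) {
    double cur = dp[i][j];
    bool clip_here = (j == 0 && at_start && i <= ((int)read.size() < 1 ? 0 : max_clip)) ||
                     (j == W && at_end && i >= (int)read.size() - max_clip + 1);
    if (clip_here && dp[i - 1][j] < INF_COST && cur == dp[i - 1][j]) {
      --i; // soft-clipped read base
    } else if (j > 0 && dp[i - 1][j - 1] < INF_COST &&
               cur == dp[i - 1][j - 1] +
                 (read[i - 1] == gene[g0 + j - 1] ? 0.0 : mismatch_cost)) {
      if (read[i - 1] == gene[g0 + j - 1]) ++matches;
      ++columns; ++read_aligned; --i; --j;
    } else if (j > 0 && dp[i][j - 1] < INF_COST &&
               cur == dp[i][j - 1] + indel_cost) {
      ++columns; --j;
    } else if (dp[i - 1][j] < INF_COST && cur == dp[i - 1][j] + indel_cost) {
      ++columns; ++read_aligned; --i;
    } else {
      return false;
    }
  }
  cost = cbest;
  identity = columns > 0 ? (double)matches / (double)columns : 0.0;
  length_fraction = (double)read_aligned / (double)L;
  return true;
}

static inline uint64_t encode_base(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default: return 4;
  }
}

// [[Rcpp::export(name = ".assign_reads_cpp")]]
List assign_reads_cpp(CharacterVector reads, CharacterVector genes,
                      double min_similarity, double min_length_fraction,
                      double mismatch_cost, double indel_cost, int kmer) {
  const int nG = genes.size();
  std::vector<std::string> G(nG);
  for (int g = 0; g < nG; ++g) G[g] = as<std::string>(genes[g]);

  // k-mer index over genes: key -> vector of (gene, pos)
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  const uint64_t kmask = (kmer < 32) ? ((1ULL << (2 * kmer)) - 1) : ~0ULL;
  for (int g = 0; g < nG; ++g) {
    const std::string &s = G[g];
    if ((int)s.size() < kmer) continue;
    uint64_t key = 0; int valid = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      uint64_t b = encode_base(s[p]);
      if (b > 3) { valid = 0; key = 0; continue; }
      key = ((key << 2) | b) & kmask;
      if (++valid >= kmer) index[key].push_back({g, p - kmer + 1});
    }
  }

  const int nR = reads.size();
  IntegerVector best_gene(nR, NA_INTEGER);
  NumericVector best_cost(nR, NA_REAL);
  NumericVector best_identity(nR, NA_REAL);
  IntegerVector n_best(nR, 0);
  List tied(nR);

  for (int r = 0; r < nR; ++r) {
    std::string rd = as<std::string>(reads[r]);
    int L = (int)rd.size();
    if (L < kmer) continue;
    // sample seeds across the read
    std::vector<int> seed_pos;
    for (int p = 0; p + kmer <= L; p += kmer) seed_pos.push_back(p);
    if (seed_pos.empty() || seed_pos.back() != L - kmer)
      seed_pos.push_back(L - kmer);
    // candidate (gene, gstart) placements
    std::vector<std::pair<int, int>> cands;
    for (int p : seed_pos) {
      uint64_t key = 0; bool ok = true;
      for (int t = 0; t < kmer; ++t) {
        uint64_t b = encode_base(rd[p + t]);
        if (b > 3) { ok = false; break; }
        key = ((key << 2) | b) & kmask;
      }
      if (!ok) continue;
      auto it = index.find(key);
      if (it == index.end()) continue;
      for (auto &gp : it->second) cands.push_back({gp.first, gp.second - p});
    }
    std::sort(cands.begin(), cands.end());
    // merge near-identical diagonals per gene, counting seed votes,
    // then keep only the best-voted few diagonals of each gene --
    // repetitive regions (poly-Q codon runs) otherwise spawn hundreds of
    // shifted placements per gene
    struct Plc { int gene; int diag; int votes; };
    std::vector<Plc> merged;
    for (size_t c = 0; c < cands.size(); ++c) {
      if (!merged.empty() && merged.back().gene == cands[c].first &&
          std::abs(merged.back().diag - cands[c].second) <= BAND) {
        ++merged.back().votes;
        continue;
      }
      merged.push_back({cands[c].first, cands[c].second, 1});
    }
    std::vector<std::pair<int, int>> placements;
    size_t lo = 0;
    while (lo < merged.size()) {
      size_t hi = lo;
      while (hi < merged.size() && merged[hi].gene == merged[lo].gene) ++hi;
      // top 3 diagonals by votes for this gene (stable for determinism)
      std::vector<size_t> ord;
      for (size_t t = lo; t < hi; ++t) ord.push_back(t);
      std::stable_sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
        return merged[a].votes > merged[b].votes;
      });
      for (size_t t = 0; t < ord.size() && t < 3; ++t)
        placements.push_back({merged[ord[t]].gene, merged[ord[t]].diag});
      lo = hi;
    }
    double bc = INF_COST;
    std::vector<int> bg;
    std::vector<double> bid;
    for (auto &pl : placements) {
      double cost, id, lf;
      int max_clip = (int)std::floor((1.0 - min_length_fraction) * L);
      if (!banded_align(rd, G[pl.first], pl.second, mismatch_cost,
                        indel_cost, max_clip, cost, id, lf))
        continue;
      if (id < min_similarity || lf < min_length_fraction) continue;
      if (cost < bc - 1e-9) {
        bc = cost; bg.clear(); bid.clear();
        bg.push_back(pl.first); bid.push_back(id);
      } else if (std::abs(cost - bc) <= 1e-9) {
        if (std::find(bg.begin(), bg.end(), pl.first) == bg.end()) {
          bg.push_back(pl.first); bid.push_back(id);
        }
      }
    }
    if (!bg.empty()) {
      best_gene[r] = bg[0] + 1;  // 1-based for R
      best_cost[r] = bc;
      best_identity[r] = bid[0];
      n_best[r] = (int)bg.size();
      if (bg.size() > 1) {
        IntegerVector tg(bg.size());
        for (size_t t = 0; t < bg.size(); ++t) tg[t] = bg[t] + 1;
        tied[r] = tg;
      }
    }
  }
  return List::create(_["gene"] = best_gene, _["cost"] = best_cost,
                      _["identity"] = best_identity, _["n_best"] = n_best,
                      _["tied"] = tied);
}
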