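#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with unit mismatch cost and a uniform
// gap-column penalty. Terminal gaps are penalized during construction (this
// keeps the optimization non-degenerate) but terminal-gap columns are excluded
// from the reported statistics, so sequences identical up to end gaps score a
// dissimilarity of exactly 0.
//
// Optimal path selection is lexicographic: minimal total cost, then maximal
// match count, then minimal gap-column count; ties between directions resolved
// diagonal > up > left. This makes the reported (matches, mismatches, gaps)
// triple deterministic.

struct AlnStats {
  int matches;
  int mismatches;
  int gapcols; // internal gap columns only
};

static AlnStats align_stats_one(const std::string& a0, const std::string& b0,
                                double gap_penalty) {
  // canonical argument order: tied optimal paths can differ in how much of
  // their gap run is terminal, so symmetry d(a,b) = d(b,a) is enforced by
  // always aligning the lexicographically smaller sequence first
  const std::string& a = (a0 <= b0) ? a0 : b0;
  const std::string& b = (a0 <= b0) ? b0 : a0;
  const int m = (int)a.size(), n = (int)b.size();
  const int W = n + 1;
  std::vector<double> cost((m + 1) * W);
  std::vector<int> match((m + 1) * W), gaps((m + 1) * W);
  std::vector<unsigned char> dir((m + 1) * W); // 0 stop, 1 diag, 2 up, 3 left

  cost[0] = 0; match[0] = 0; gaps[0] = 0; dir[0] = 0;
  for (int j = 1; j <= n; ++j) {
    cost[j] = j * gap_penalty; match[j] = 0; gaps[j] = j; dir[j] = 3;
  }
  for (int i = 1; i <= m; ++i) {
    cost[i * W] = i * gap_penalty; match[i * W] = 0; gaps[i * W] = i;
    dir[i * W] = 2;
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int here = i * W + j;
      const bool eq = a[i - 1] == b[j - 1];
      // candidate: diagonal
      double c = cost[here - W - 1] + (eq ? 0.0 : 1.0);
      int mt = match[here - W - 1] + (eq ? 1 : 0);
      int gp = gaps[here - W - 1];
      unsigned char d = 1;
      // candidate: up (gap in b)
      double c2 = cost[here - W] + gap_penalty;
      int mt2 = match[here - W], gp2 = gaps[here - W] + 1;
      if (c2 < c || (c2 == c && (mt2 > mt || (mt2 == mt && gp2 < gp)))) {
        c = c2; mt = mt2; gp = gp2; d = 2;
      }
      // candidate: left (gap in a)
      double c3 = cost[here - 1] + gap_penalty;
      int mt3 = match[here - 1], gp3 = gaps[here - 1] + 1;
      if (c3 < c || (c3 == c && (mt3 > mt || (mt3 == mt && gp3 < gp)))) {
        c = c3; mt = mt3; gp = gp3; d = 3;
      }
      cost[here] = c; match[here] = mt; gaps[here] = gp; dir[here] = d;
    }
  }

  // traceback: column types from end to start (1 = match, 0 = mismatch,
  // 2 = gap)
  std::vector<unsigned char> cols;
  cols.reserve(m + n);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    unsigned char d = dir[i * W + j];
    if (d == 1) {
      cols.push_back(a[i - 1] == b[j - 1] ? 1 : 0);
      --i; --j;
    } else if (d == 2) {
      cols.push_back(2);
      --i;
    } else {
      cols.push_back(2);
      --j;
    }
  }
  // strip terminal gap runs (cols currently reversed; runs at both ends)
  int lo = 0, hi = (int)cols.size() - 1;
  while (lo <= hi && cols[lo] == 2) ++lo;
  while (hi >= lo && cols[hi] == 2) --hi;
  AlnStats s = {0, 0, 0};
  for (int k = lo; k <= hi; ++k) {
    if (cols[k] == 1) ++s.matches;
    else if (cols[k] == 0) ++s.mismatches;
    else ++s.gapcols;
  }
  return s;
}

static double dissim_from_stats(const AlnStats& s, double gap_penalty) {
  const int ncol = s.matches + s.mismatches + s.gapcols;
  if (ncol == 0) return 1.0;
  return (s.mismatches + gap_penalty * s.gapcols) / (double)ncol;
}

// [[Rcpp::export]]
IntegerVector align_stats_cpp(std::string a, std::string b,
                              double gap_penalty) {
  AlnStats s = align_stats_one(a, b, gap_penalty);
  return IntegerVector::create(_["matches"] = s.matches,
                               _["mismatches"] = s.mismatches,
                               _["gapcols"] = s.gapcols);
}

// [[Rcpp::export]]
NumericVector pair_dissim_cpp(CharacterVector seqs, IntegerVector i,
                              IntegerVector j, double gap_penalty) {
  const int np = i.size();
  std::vector<std::string> ss(seqs.size());
  for (int k = 0; k < seqs.size(); ++k) ss[k] = as<std::string>(seqs[k]);
  NumericVector out(np);
  for (int k = 0; k < np; ++k) {
    AlnStats s = align_stats_one(ss[i[k] - 1], ss[j[k] - 1], gap_penalty);
    out[k] = dissim_from_stats(s, gap_penalty);
  }
  return out;
}

// k-mer word sets (2-bit encoded, words containing non-ACGT skipped)
static std::vector<uint32_t> kmer_set(const std::string& s, int k) {
  std::vector<uint32_t> words;
  const int n = (int)s.size();
  if (n < k) return words;
  uint32_t w = 0, mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int code;
    switch (s[i]) {
      case 'A': case 'a': code = 0; break;
      case 'C': case 'c': code = 1; break;
      case 'G': case 'g': code = 2; break;
      case 'T': case 't': code = 3; break;
      default: code = -1;
    }
    if (code < 0) { run = 0; w = 0; continue; }
    w = ((w << 2) | (uint32_t)code) & mask;
    if (++run >= k) words.push_back(w);
  }
  std::sort(words.begin(), words.end());
  words.erase(std::unique(words.begin(), words.end()), words.end());
  return words;
}

// [[Rcpp::export]]
IntegerMatrix kmer_candidate_pairs_cpp(CharacterVector seqs, int k,
                                       double cutoff) {
  const int n = seqs.size();
  std::vector<std::vector<uint32_t> > sets(n);
  for (int s = 0; s < n; ++s) sets[s] = kmer_set(as<std::string>(seqs[s]), k);
  std::vector<int> ii, jj;
  std::vector<uint32_t> tmp;
  for (int a = 0; a < n - 1; ++a) {
    for (int b = a + 1; b < n; ++b) {
      const size_t na = sets[a].size(), nb = sets[b].size();
      double shared = 0.0;
      if (na > 0 && nb > 0) {
        tmp.clear();
        std::set_intersection(sets[a].begin(), sets[a].end(), sets[b].begin(),
                              sets[b].end(), std::back_inserter(tmp));
        shared = (double)tmp.size() / (double)std::min(na, nb);
      }
      if (1.0 - shared <= cutoff) {
        ii.push_back(a + 1);
        jj.push_back(b + 1);
      }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t r = 0; r < ii.size(); ++r) {
    out(r, 0) = ii[r];
    out(r, 1) = jj[r];
  }
  return out;
}
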