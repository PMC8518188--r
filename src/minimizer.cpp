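#include "seq_utils.h"
#include <deque>
#include <algorithm>
using namespace Rcpp;

struct Mini { int pos; uint64_t hash; bool rc; };

// Leftmost-lowest canonical minimizer per window of w consecutive k-mers;
// consecutive duplicate (pos, hash) selections deduplicated.
static std::vector<Mini> minimizers_of(const std::string& seq, int k, int w) {
  std::vector<Mini> kmers;
  kmers.reserve(seq.size());
  for_each_canonical_kmer(seq, k, [&](int p, uint64_t h, bool rc) {
    kmers.push_back({p, h, rc});
  });
  std::vector<Mini> out;
  if (kmers.empty()) return out;
  if ((int)kmers.size() <= 0) return out;
  std::deque<int> dq; // indices into kmers, increasing pos, increasing hash
  size_t j = 0;
  int last_pos = -1;
  // windows are over *valid* consecutive k-mer start positions; an N gap
  // resets the run (positions are not consecutive there).
  std::vector<std::pair<size_t, size_t>> runs; // [begin, end) in kmers
  size_t b = 0;
  for (size_t i = 1; i <= kmers.size(); ++i) {
    if (i == kmers.size() || kmers[i].pos != kmers[i - 1].pos + 1) {
      runs.push_back({b, i});
      b = i;
    }
  }
  for (auto& run : runs) {
    dq.clear();
    for (size_t i = run.first; i < run.second; ++i) {
      while (!dq.empty() && kmers[dq.back()].hash > kmers[i].hash) dq.pop_back();
      dq.push_back((int)i);
      while (kmers[dq.front()].pos <= kmers[i].pos - w) dq.pop_front();
      size_t in_run = i - run.first + 1;
      if ((int)in_run >= w || i + 1 == run.second) {
        // emit current window minimizer (also emit once for short runs)
        int sel = dq.front();
        if (kmers[sel].pos != last_pos) {
          out.push_back(kmers[sel]);
          last_pos = kmers[sel].pos;
        }
      }
    }
  }
  (void)j;
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_minimizers(std::string seq, int k, int w) {
  if (k < 1 || k > 25) stop("k must be in 1..25");
  if (w < 1) stop("w must be >= 1");
  std::vector<Mini> ms = minimizers_of(seq, k, w);
  int n = (int)ms.size();
  IntegerVector pos(n), rc(n);
  NumericVector hash(n);
  for (int i = 0; i < n; ++i) {
    pos[i] = ms[i].pos;
    hash[i] = (double)ms[i].hash;
    rc[i] = ms[i].rc ? 1 : 0;
  }
  return DataFrame::create(_["pos"] = pos, _["hash"] = hash, _["rc"] = rc);
}

// Assign read groups to bins by distinct shared canonical minimizers.
// idx_hash: sorted (ascending, with duplicates when a hash occurs in several
// bins) hash values; idx_bin: parallel 1-based bin ids. group: 1-based group
// id per read (mates of a pair share a group and are scored jointly; distinct
// shared minimizers are counted per read, summed over the group).
// Returns per group (1..max(group)): best bin (0 if none scored), score,
// runner_up.
// [[Rcpp::export]]
List cpp_assign_minimizers(CharacterVector reads, IntegerVector group,
                           NumericVector idx_hash, IntegerVector idx_bin,
                           int k, int w, int n_bins) {
  int n = reads.size();
  int ng = 0;
  for (int i = 0; i < n; ++i) ng = std::max(ng, group[i]);
  IntegerVector best(ng), score(ng), runner(ng), nmin(ng);
  std::vector<int> binscore(n_bins + 1, 0);
  std::vector<int> touched;
  const double* H = REAL(idx_hash);
  const int m = idx_hash.size();
  // reads of one group are assumed contiguous after R-side ordering
  std::vector<std::vector<int>> members(ng + 1);
  for (int i = 0; i < n; ++i) members[group[i]].push_back(i);
  for (int g = 1; g <= ng; ++g) {
    touched.clear();
    for (int i : members[g]) {
      std::string s = as<std::string>(reads[i]);
      std::vector<Mini> ms = minimizers_of(s, k, w);
      std::vector<double> hs;
      hs.reserve(ms.size());
      for (auto& mm : ms) hs.push_back((double)mm.hash);
      std::sort(hs.begin(), hs.end());
      hs.erase(std::unique(hs.begin(), hs.end()), hs.end());
      nmin[g - 1] += (int)hs.size();
      for (double h : hs) {
        const double* lo = std::lower_bound(H, H + m, h);
        for (const double* p = lo; p < H + m && *p == h; ++p) {
          int b = idx_bin[(int)(p - H)];
          if (binscore[b] == 0) touched.push_back(b);
          binscore[b] += 1;
        }
      }
    }
    std::sort(touched.begin(), touched.end()); // deterministic tie order
    touched.erase(std::unique(touched.begin(), touched.end()), touched.end());
    int b1 = 0, s1 = 0, s2 = 0;
    for (int b : touched) {
      int sc = binscore[b];
      if (sc > s1) { s2 = s1; s1 = sc; b1 = b; }
      else if (sc > s2) { s2 = sc; }
    }
    for (int b : touched) binscore[b] = 0;
    best[g - 1] = b1; score[g - 1] = s1; runner[g - 1] = s2;
  }
  return List::create(_["bin"] = best, _["score"] = score,
                      _["runner_up"] = runner, _["n_min"] = nmin);
}
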