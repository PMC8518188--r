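#include "seq_utils.h"
#include <deque>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// shares minimizer machinery with minimizer.cpp (duplicated small helper to
// keep translation units independent)
namespace {
struct MiniO { int pos; uint64_t hash; bool rc; };

std::vector<MiniO> minis(const std::string& seq, int k, int w) {
  std::vector<MiniO> kmers;
  kmers.reserve(seq.size());
  for_each_canonical_kmer(seq, k, [&](int p, uint64_t h, bool rc) {
    kmers.push_back({p, h, rc});
  });
  std::vector<MiniO> out;
  if (kmers.empty()) return out;
  std::vector<std::pair<size_t, size_t>> runs;
  size_t b = 0;
  for (size_t i = 1; i <= kmers.size(); ++i)
    if (i == kmers.size() || kmers[i].pos != kmers[i - 1].pos + 1) { runs.push_back({b, i}); b = i; }
  std::deque<int> dq;
  int last_pos = -1;
  for (auto& run : runs) {
    dq.clear();
    for (size_t i = run.first; i < run.second; ++i) {
      while (!dq.empty() && kmers[dq.back()].hash > kmers[i].hash) dq.pop_back();
      dq.push_back((int)i);
      while (kmers[dq.front()].pos <= kmers[i].pos - w) dq.pop_front();
      if ((int)(i - run.first + 1) >= w || i + 1 == run.second) {
        int sel = dq.front();
        if (kmers[sel].pos != last_pos) { out.push_back(kmers[sel]); last_pos = kmers[sel].pos; }
      }
    }
  }
  return out;
}

struct Hit { int pa, pb; };
} // namespace

// All-vs-all candidate overlaps between sequences by shared-minimizer
// diagonal chaining. Returns one row per (a < b, best orientation):
//   a, b       1-based sequence indices
//   orient     0 = same strand, 1 = b reverse-complemented
//   diag       offset d with a_pos ~= b'_pos + d (b' = oriented b)
//   ov_len     implied overlap length (bp)
//   score      chained minimizer count
//   span       chained span on a (bp)
// [[Rcpp::export]]
DataFrame cpp_find_overlaps(CharacterVector seqs, int k, int w, int max_occ,
                            int band, int min_chain, int min_overlap) {
  const int n = seqs.size();
  std::vector<int> len(n);
  std::vector<std::vector<MiniO>> mm(n);
  // hash -> occurrences (read, pos, rc)
  struct Occ { int read, pos; bool rc; };
  std::unordered_map<uint64_t, std::vector<Occ>> table;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    len[i] = (int)s.size();
    mm[i] = minis(s, k, w);
    for (auto& m : mm[i]) table[m.hash].push_back({i, m.pos, m.rc});
  }
  // pair hits keyed by (a, b, rel)
  std::unordered_map<uint64_t, std::vector<Hit>> pairs;
  for (auto& kv : table) {
    auto& v = kv.second;
    if ((int)v.size() > max_occ) continue;
    for (size_t x = 0; x < v.size(); ++x)
      for (size_t y = x + 1; y < v.size(); ++y) {
        const Occ *pa = &v[x], *pb = &v[y];
        if (pa->read == pb->read) continue;
        if (pa->read > pb->read) std::swap(pa, pb);
        int rel = (pa->rc != pb->rc) ? 1 : 0;
        // position of the k-mer on oriented b (reverse complement flips coords)
        int pbp = rel ? (len[pb->read] - k - pb->pos) : pb->pos;
        uint64_t key = ((uint64_t)pa->read << 33) | ((uint64_t)pb->read << 1) | (uint64_t)rel;
        pairs[key].push_back({pa->pos, pbp});
      }
  }
  std::vector<int> ra, rb, ror, rdiag, rov, rsc, rspan;
  // deterministic iteration: collect and sort keys
  std::vector<uint64_t> keys;
  keys.reserve(pairs.size());
  for (auto& kv : pairs) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  // best orientation per (a,b)
  std::unordered_map<uint64_t, size_t> best_row;
  for (uint64_t key : keys) {
    auto& hits = pairs[key];
    if ((int)hits.size() < min_chain) continue;
    int a = (int)(key >> 33), b = (int)((key >> 1) & 0xFFFFFFFFULL), rel = (int)(key & 1);
    // cluster by diagonal
    std::sort(hits.begin(), hits.end(), [](const Hit& u, const Hit& v) {
      return (u.pa - u.pb) < (v.pa - v.pb);
    });
    // find densest diagonal window of width `band`
    size_t bi = 0, bestc = 0, blo = 0, bhi = 0;
    for (size_t i = 0, j = 0; i < hits.size(); ++i) {
      int di = hits[i].pa - hits[i].pb;
      while ((hits[i].pa - hits[i].pb) - (hits[j].pa - hits[j].pb) > band) ++j;
      (void)di;
      if (i - j + 1 > bestc) { bestc = i - j + 1; blo = j; bhi = i; bi = j; }
    }
    (void)bi;
    if ((int)bestc < min_chain) continue;
    std::vector<Hit> cl(hits.begin() + blo, hits.begin() + bhi + 1);
    std::sort(cl.begin(), cl.end(), [](const Hit& u, const Hit& v) {
      return u.pa < v.pa || (u.pa == v.pa && u.pb < v.pb);
    });
    // greedy colinear chain
    int cnt = 0, lastpa = -1, lastpb = -1, minpa = 0, maxpa = 0;
    long dsum = 0;
    for (auto& h : cl) {
      if (cnt == 0 || (h.pa > lastpa && h.pb > lastpb)) {
        if (cnt == 0) minpa = h.pa;
        maxpa = h.pa;
        lastpa = h.pa; lastpb = h.pb;
        dsum += (h.pa - h.pb);
        ++cnt;
      }
    }
    if (cnt < min_chain) continue;
    int d = (int)(dsum / cnt);
    int ov = std::min(len[a], len[b] + d) - std::max(0, d);
    if (ov < min_overlap) continue;
    int span = maxpa + k - minpa;
    if (span < ov / 3) continue; // sparse/spurious chain
    uint64_t ab = ((uint64_t)a << 32) | (uint64_t)b;
    auto it = best_row.find(ab);
    if (it != best_row.end()) {
      if (rsc[it->second] >= cnt) continue;
      ra[it->second] = a + 1; rb[it->second] = b + 1; ror[it->second] = rel;
      rdiag[it->second] = d; rov[it->second] = ov; rsc[it->second] = cnt;
      rspan[it->second] = span;
      continue;
    }
    best_row[ab] = ra.size();
    ra.push_back(a + 1); rb.push_back(b + 1); ror.push_back(rel);
    rdiag.push_back(d); rov.push_back(ov); rsc.push_back(cnt); rspan.push_back(span);
  }
  return DataFrame::create(_["a"] = ra, _["b"] = rb, _["orient"] = ror,
                           _["diag"] = rdiag, _["ov_len"] = rov,
                           _["score"] = rsc, _["span"] = rspan);
}
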