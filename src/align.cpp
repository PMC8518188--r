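#include "seq_utils.h"
#include <unordered_map>
#include <map>
#include <algorithm>
using namespace Rcpp;

namespace {

struct AlnStats { long matches = 0, mism = 0, ins = 0, del = 0; };

// Banded global (Needleman-Wunsch, unit costs) alignment of q against r.
// Emits columns via emit(op, qpos, rpos): op 'M' consumes both (match or
// mismatch), 'I' consumes a query base (extra in query, placed before rpos),
// 'D' consumes a ref base. If free_ref_end, the ref suffix may stay
// unaligned (alignment ends at the best column of the last row).
// Returns false if the band/memory guard trips.
template <typename Emit>
bool nw_seg(const std::string& q, const std::string& r, int band,
            AlnStats& st, Emit emit, bool free_ref_end = false) {
  const int m = (int)q.size(), n = (int)r.size();
  if (m == 0) {
    if (!free_ref_end) for (int j = 0; j < n; ++j) { st.del++; emit('D', 0, j); }
    return true;
  }
  if (n == 0) { for (int i = 0; i < m; ++i) { st.ins++; emit('I', i, 0); } return true; }
  const int dmin = std::min(0, n - m), dmax = std::max(0, n - m);
  const int W = dmax - dmin + 2 * band + 1;
  if ((double)(m + 1) * W > 2.5e8) return false;
  auto jlo = [&](int i) { return std::max(0, i + dmin - band); };
  auto jhi = [&](int i) { return std::min(n, i + dmax + band); };
  const int INF = 1 << 28;
  std::vector<int> prev(W + 2, INF), cur(W + 2, INF);
  std::vector<uint8_t> tb((size_t)(m + 1) * W);
  for (int j = jlo(0); j <= jhi(0); ++j) { prev[j - jlo(0)] = j; tb[j - jlo(0)] = 2; }
  for (int i = 1; i <= m; ++i) {
    int lo = jlo(i), hi = jhi(i), plo = jlo(i - 1), phi = jhi(i - 1);
    std::fill(cur.begin(), cur.end(), INF);
    uint8_t* trow = &tb[(size_t)i * W];
    for (int j = lo; j <= hi; ++j) {
      int best = INF; uint8_t op = 0;
      if (j - 1 >= plo && j - 1 <= phi) { // diag preferred on ties
        int v = prev[j - 1 - plo] + ((q[i - 1] == r[j - 1]) ? 0 : 1);
        if (v < best) { best = v; op = 0; }
      }
      if (j >= plo && j <= phi) { // up: query gap (I)
        int v = prev[j - plo] + 1;
        if (v < best) { best = v; op = 1; }
      }
      if (j - 1 >= lo) { // left: ref gap (D)
        int v = cur[j - 1 - lo] + 1;
        if (v < best) { best = v; op = 2; }
      }
      cur[j - lo] = best;
      trow[j - lo] = op;
    }
    std::swap(prev, cur);
  }
  int jend = n;
  if (free_ref_end) {
    int bc = INF;
    for (int j = jlo(m); j <= jhi(m); ++j)
      if (prev[j - jlo(m)] < bc) { bc = prev[j - jlo(m)]; jend = j; }
    if (bc >= INF) return false;
  } else if (prev[n - jlo(m)] >= INF) return false;
  std::vector<uint8_t> ops;
  ops.reserve(m + n);
  int i = m, j = jend;
  while (i > 0 || j > 0) {
    uint8_t op;
    if (i == 0) { if (free_ref_end) break; op = 2; }
    else if (j == 0) op = 1;
    else op = tb[(size_t)i * W + (j - jlo(i))];
    ops.push_back(op);
    if (op == 0) { --i; --j; }
    else if (op == 1) { --i; }
    else { --j; }
  }
  int i0 = i, j0 = j; // for free_ref_end with i==0, ref prefix [0,j0) unaligned
  if (!free_ref_end) { i0 = 0; j0 = 0; }
  std::reverse(ops.begin(), ops.end());
  i = i0; j = j0;
  for (uint8_t op : ops) {
    if (op == 0) {
      if (q[i] == r[j]) st.matches++; else st.mism++;
      emit('M', i, j); ++i; ++j;
    } else if (op == 1) { st.ins++; emit('I', i, j); ++i; }
    else { st.del++; emit('D', i, j); ++j; }
  }
  return true;
}

struct Run { int q0, r0, len; }; // exact-match runs from anchors

// Merge colinear anchors (strictly increasing q and r) into exact runs, then
// trim run overlaps so inter-run segments are non-negative on both sides.
std::vector<Run> merge_runs(const std::vector<int>& qp, const std::vector<int>& rp, int k) {
  std::vector<Run> runs;
  for (size_t i = 0; i < qp.size(); ++i) {
    if (!runs.empty()) {
      Run& c = runs.back();
      if (qp[i] - c.q0 == rp[i] - c.r0 && qp[i] <= c.q0 + c.len) {
        c.len = qp[i] + k - c.q0;
        continue;
      }
    }
    runs.push_back({qp[i], rp[i], k});
  }
  // trim overlaps between consecutive runs on different diagonals
  std::vector<Run> out;
  for (Run r : runs) {
    while (!out.empty()) {
      Run& p = out.back();
      int ov = std::max(p.q0 + p.len - r.q0, p.r0 + p.len - r.r0);
      if (ov <= 0) break;
      p.len -= ov;
      if (p.len <= 0) { out.pop_back(); continue; }
      break;
    }
    out.push_back(r);
  }
  return out;
}

int seg_band(int lq, int lr, int band_min) {
  return band_min + (int)(0.25 * std::max(lq, lr)) + std::abs(lq - lr);
}

} // namespace

// Semi-global alignment: all of `query` against a free substring of `ref`
// (unit costs, full DP, cost-only with start tracking). Returns the best
// (rstart, rend) half-open ref interval and the edit distance.
// [[Rcpp::export]]
List cpp_locate_prefix(std::string query, std::string ref) {
  const int m = (int)query.size(), n = (int)ref.size();
  if (m == 0 || n == 0) return List::create(_["rstart"] = 0, _["rend"] = 0, _["edits"] = m);
  std::vector<int> dp(n + 1), st(n + 1), ndp(n + 1), nst(n + 1);
  for (int j = 0; j <= n; ++j) { dp[j] = 0; st[j] = j; }
  for (int i = 1; i <= m; ++i) {
    ndp[0] = i; nst[0] = 0;
    for (int j = 1; j <= n; ++j) {
      int vdiag = dp[j - 1] + ((query[i - 1] == ref[j - 1]) ? 0 : 1);
      int vup = dp[j] + 1;
      int vleft = ndp[j - 1] + 1;
      if (vdiag <= vup && vdiag <= vleft) { ndp[j] = vdiag; nst[j] = st[j - 1]; }
      else if (vup <= vleft) { ndp[j] = vup; nst[j] = st[j]; }
      else { ndp[j] = vleft; nst[j] = nst[j - 1]; }
    }
    dp.swap(ndp); st.swap(nst);
  }
  int bj = 0, bc = 1 << 28;
  for (int j = 0; j <= n; ++j) if (dp[j] < bc) { bc = dp[j]; bj = j; }
  return List::create(_["rstart"] = st[bj], _["rend"] = bj, _["edits"] = bc);
}

// Anchor hits: positions where a canonical k-mer of `query` equals a
// canonical k-mer occurring exactly once in `ref`. strand +1 means the
// forward query strand matches the forward ref strand at that k-mer.
// [[Rcpp::export]]
DataFrame cpp_anchor_hits(std::string query, std::string ref, int k) {
  std::unordered_map<uint64_t, std::pair<int, int>> refmap; // canon -> (pos, rc); pos -2 if dup
  for_each_canonical_kmer(ref, k, [&](int p, uint64_t h, bool rc) {
    auto it = refmap.find(h);
    if (it == refmap.end()) refmap[h] = {p, rc ? 1 : 0};
    else it->second.first = -2;
  });
  std::vector<int> qp, rp, strand;
  for_each_canonical_kmer(query, k, [&](int p, uint64_t h, bool rcq) {
    auto it = refmap.find(h);
    if (it == refmap.end() || it->second.first < 0) return;
    qp.push_back(p);
    rp.push_back(it->second.first);
    strand.push_back((rcq == (it->second.second == 1)) ? 1 : -1);
  });
  return DataFrame::create(_["qpos"] = qp, _["rpos"] = rp, _["strand"] = strand);
}

// Alignment statistics along a colinear anchor chain. qpos/rpos: 0-based,
// strictly increasing, exact k-mer matches of query vs ref (same strand;
// callers orient the query first). Inter-anchor gaps are aligned with a
// banded NW; if extend_ends, the query head/tail beyond the outermost anchors
// is aligned against the adjacent ref sequence with a free ref end.
// Returns block bounds and match/mismatch/indel counts.
// [[Rcpp::export]]
List cpp_chain_stats(std::string query, std::string ref, IntegerVector qpos,
                     IntegerVector rpos, int k, int band_min,
                     bool extend_ends = true, int max_ext = 20000) {
  std::vector<int> qp(qpos.begin(), qpos.end()), rp(rpos.begin(), rpos.end());
  if (qp.empty()) stop("empty anchor chain");
  std::vector<Run> runs = merge_runs(qp, rp, k);
  AlnStats st;
  bool ok = true;
  for (size_t i = 0; i < runs.size(); ++i) {
    st.matches += runs[i].len;
    if (i + 1 < runs.size()) {
      int q0 = runs[i].q0 + runs[i].len, q1 = runs[i + 1].q0;
      int r0 = runs[i].r0 + runs[i].len, r1 = runs[i + 1].r0;
      std::string qs = query.substr(q0, q1 - q0), rs = ref.substr(r0, r1 - r0);
      ok = nw_seg(qs, rs, seg_band((int)qs.size(), (int)rs.size(), band_min), st,
                  [](char, int, int) {}) && ok;
    }
  }
  if (!ok) stop("alignment band/memory guard exceeded");
  int qs0 = runs.front().q0, qe = runs.back().q0 + runs.back().len;
  int rs0 = runs.front().r0, re = runs.back().r0 + runs.back().len;
  if (extend_ends) {
    int qn = (int)query.size(), rn = (int)ref.size();
    if (qs0 > 0 && qs0 <= max_ext && rs0 > 0) {
      std::string qh(query.rbegin() + (qn - qs0), query.rend());
      int rlen = std::min(rs0, qs0 + 50 + qs0 / 4);
      std::string rh(ref.rbegin() + (rn - rs0), ref.rbegin() + (rn - rs0 + rlen));
      AlnStats eh;
      int rused = 0;
      if (nw_seg(qh, rh, seg_band((int)qh.size(), (int)rh.size(), band_min), eh,
                 [&](char op, int, int rj) { if (op != 'I') rused = std::max(rused, rj + 1); },
                 true)) {
        st.matches += eh.matches; st.mism += eh.mism; st.ins += eh.ins; st.del += eh.del;
        qs0 = 0; rs0 -= rused;
      }
    }
    if (qe < qn && (qn - qe) <= max_ext && re < rn) {
      std::string qt = query.substr(qe);
      int rlen = std::min(rn - re, (qn - qe) + 50 + (qn - qe) / 4);
      std::string rt = ref.substr(re, rlen);
      AlnStats et;
      int rused = 0;
      if (nw_seg(qt, rt, seg_band((int)qt.size(), (int)rt.size(), band_min), et,
                 [&](char op, int, int rj) { if (op != 'I') rused = std::max(rused, rj + 1); },
                 true)) {
        st.matches += et.matches; st.mism += et.mism; st.ins += et.ins; st.del += et.del;
        qe = qn; re += rused;
      }
    }
  }
  return List::create(_["qstart"] = qs0, _["qend"] = qe, _["rstart"] = rs0,
                      _["rend"] = re, _["matches"] = (double)st.matches,
                      _["mismatches"] = (double)st.mism,
                      _["insertions"] = (double)st.ins,
                      _["deletions"] = (double)st.del);
}

// Consensus polishing by anchored pileup. Reads are anchored to the draft by
// unique canonical k_anchor-mers on their majority strand, colinear anchors
// are chained, inter-anchor gaps and the read head/tail are aligned in a band
// (band_min extra). Per-column votes (base/deletion, plus insertions keyed to
// the following draft position) are applied where coverage >= min_depth and
// the winning call has >= min_frac of the votes; elsewhere the draft base is
// kept. Returns the polished sequence and the number of anchored reads.
// [[Rcpp::export]]
List cpp_pileup_polish(std::string draft, CharacterVector reads, int k_anchor,
                       int band_min, int min_depth, double min_frac,
                       int min_anchors) {
  const int L = (int)draft.size();
  std::unordered_map<uint64_t, std::pair<int, int>> refmap;
  refmap.reserve(L * 2);
  for_each_canonical_kmer(draft, k_anchor, [&](int p, uint64_t h, bool rc) {
    auto it = refmap.find(h);
    if (it == refmap.end()) refmap[h] = {p, rc ? 1 : 0};
    else it->second.first = -2;
  });
  std::vector<int> votes((size_t)L * 5, 0); // A C G T del
  std::unordered_map<int, std::map<std::string, int>> insmap;
  int n_anch = 0;
  for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    std::vector<int> qf, rf, sf;
    for_each_canonical_kmer(rd, k_anchor, [&](int p, uint64_t h, bool rcq) {
      auto it = refmap.find(h);
      if (it == refmap.end() || it->second.first < 0) return;
      qf.push_back(p); rf.push_back(it->second.first);
      sf.push_back((rcq == (it->second.second == 1)) ? 1 : -1);
    });
    if ((int)qf.size() < min_anchors) continue;
    int nplus = 0;
    for (int s : sf) if (s > 0) ++nplus;
    bool use_rc = (2 * nplus < (int)sf.size());
    std::string oriented = use_rc ? revcomp_str(rd) : rd;
    const int lr = (int)rd.size();
    std::vector<std::pair<int, int>> hits;
    for (size_t i = 0; i < qf.size(); ++i) {
      if ((sf[i] > 0) == use_rc) continue;
      int qp = use_rc ? (lr - k_anchor - qf[i]) : qf[i];
      hits.push_back({qp, rf[i]});
    }
    if ((int)hits.size() < min_anchors) continue;
    std::sort(hits.begin(), hits.end());
    std::vector<int> diags;
    diags.reserve(hits.size());
    for (auto& h : hits) diags.push_back(h.second - h.first);
    std::vector<int> ds = diags;
    std::nth_element(ds.begin(), ds.begin() + ds.size() / 2, ds.end());
    int med = ds[ds.size() / 2];
    std::vector<int> qp2, rp2;
    int lastq = -1, lastr = -1;
    for (size_t i = 0; i < hits.size(); ++i) {
      if (std::abs(diags[i] - med) > 400) continue;
      if (hits[i].first > lastq && hits[i].second > lastr) {
        qp2.push_back(hits[i].first); rp2.push_back(hits[i].second);
        lastq = hits[i].first; lastr = hits[i].second;
      }
    }
    if ((int)qp2.size() < min_anchors) continue;
    ++n_anch;
    std::vector<Run> runs = merge_runs(qp2, rp2, k_anchor);
    std::string insbuf;
    int ins_at = -1;
    bool ins_rev = false;
    auto flush_ins = [&]() {
      if (!insbuf.empty() && ins_at >= 0) {
        if (ins_rev) std::reverse(insbuf.begin(), insbuf.end());
        insmap[ins_at][insbuf]++;
      }
      insbuf.clear(); ins_at = -1;
    };
    // forward-frame vote emitter for a segment at (qoff, roff)
    auto vote_fwd = [&](const std::string& qs, int roff) {
      return [&, roff, &qs = qs](char op, int qi, int rj) {
        int rabs = roff + rj;
        if (op == 'M') {
          flush_ins();
          int c = base_code(qs[qi]);
          if (c >= 0 && rabs < L) votes[(size_t)rabs * 5 + c]++;
        } else if (op == 'D') {
          flush_ins();
          if (rabs < L) votes[(size_t)rabs * 5 + 4]++;
        } else {
          if (ins_at != rabs) flush_ins();
          ins_at = rabs; ins_rev = false;
          insbuf.push_back(qs[qi]);
        }
      };
    };
    for (size_t i = 0; i < runs.size(); ++i) {
      for (int p = runs[i].r0; p < runs[i].r0 + runs[i].len; ++p) {
        int c = base_code(draft[p]);
        if (c >= 0) votes[(size_t)p * 5 + c]++;
      }
      if (i + 1 < runs.size()) {
        int q0 = runs[i].q0 + runs[i].len, q1 = runs[i + 1].q0;
        int r0 = runs[i].r0 + runs[i].len, r1 = runs[i + 1].r0;
        if (q1 < q0 || r1 < r0) continue; // should not happen after trimming
        if (q1 - q0 > 2000 || r1 - r0 > 2000) continue; // anchor desert: no votes
        std::string qs = oriented.substr(q0, q1 - q0);
        std::string rs = draft.substr(r0, r1 - r0);
        AlnStats st;
        if (nw_seg(qs, rs, seg_band((int)qs.size(), (int)rs.size(), band_min),
                   st, vote_fwd(qs, r0)))
          flush_ins();
        else { insbuf.clear(); ins_at = -1; }
      }
    }
    // head extension (reversed frame, free draft end)
    {
      int qs0 = runs.front().q0, rs0 = runs.front().r0;
      if (qs0 > 0 && qs0 <= 2000 && rs0 > 0) {
        std::string qh(oriented.begin(), oriented.begin() + qs0);
        std::reverse(qh.begin(), qh.end());
        int rlen = std::min(rs0, qs0 + 30 + qs0 / 4);
        std::string rh(draft.begin() + (rs0 - rlen), draft.begin() + rs0);
        std::reverse(rh.begin(), rh.end());
        AlnStats st;
        if (nw_seg(qh, rh, seg_band((int)qh.size(), (int)rh.size(), band_min), st,
                   [&](char op, int qi, int rj) {
                     int rabs = rs0 - 1 - rj;
                     if (op == 'M') {
                       flush_ins();
                       int c = base_code(qh[qi]);
                       if (c >= 0 && rabs >= 0) votes[(size_t)rabs * 5 + c]++;
                     } else if (op == 'D') {
                       flush_ins();
                       if (rabs >= 0) votes[(size_t)rabs * 5 + 4]++;
                     } else {
                       int at = rs0 - rj; // insert before forward pos rs0-rj
                       if (ins_at != at) flush_ins();
                       ins_at = at; ins_rev = true;
                       insbuf.push_back(qh[qi]);
                     }
                   }, true))
          flush_ins();
        else { insbuf.clear(); ins_at = -1; }
      }
    }
    // tail extension (forward frame, free draft end)
    {
      int qe = runs.back().q0 + runs.back().len, re = runs.back().r0 + runs.back().len;
      int qn = (int)oriented.size();
      if (qe < qn && qn - qe <= 2000 && re < L) {
        std::string qt = oriented.substr(qe);
        int rlen = std::min(L - re, (qn - qe) + 30 + (qn - qe) / 4);
        std::string rt = draft.substr(re, rlen);
        AlnStats st;
        if (nw_seg(qt, rt, seg_band((int)qt.size(), (int)rt.size(), band_min),
                   st, vote_fwd(qt, re), true))
          flush_ins();
        else { insbuf.clear(); ins_at = -1; }
      }
    }
  }
  // consensus
  std::string out;
  out.reserve(L + 64);
  for (int p = 0; p <= L; ++p) {
    auto it = insmap.find(p);
    if (it != insmap.end()) {
      int cov = 0;
      int pc = std::min(p, L - 1);
      if (pc >= 0) for (int c = 0; c < 5; ++c) cov += votes[(size_t)pc * 5 + c];
      const std::string* bests = nullptr;
      int bestc = 0;
      for (auto& kv : it->second)
        if (kv.second > bestc) { bestc = kv.second; bests = &kv.first; }
      if (bests && bestc >= min_depth && bestc + 1e-9 >= min_frac * std::max(cov, bestc))
        out += *bests;
    }
    if (p == L) break;
    int cov = 0, bestc = 0, bestb = -1;
    for (int c = 0; c < 5; ++c) {
      int v = votes[(size_t)p * 5 + c];
      cov += v;
      if (v > bestc) { bestc = v; bestb = c; }
    }
    if (cov >= min_depth && bestc + 1e-9 >= min_frac * cov) {
      if (bestb < 4) out.push_back(CODE2BASE[bestb]);
    } else {
      out.push_back(draft[p]);
    }
  }
  return List::create(_["seq"] = out, _["n_anchored"] = n_anch);
}
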