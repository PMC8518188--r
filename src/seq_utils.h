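#ifndef HCBHA_SEQ_UTILS_H
#define HCBHA_SEQ_UTILS_H

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

// 2-bit base codes; anything not ACGT (upper or lower) is invalid (-1).
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

static inline std::string revcomp_str(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[s.size() - 1 - i]);
    out[i] = (c < 0) ? 'N' : CODE2BASE[3 - c];
  }
  return out;
}

// Enumerate canonical packed k-mers of seq. For every position p where the
// window seq[p, p+k) contains only ACGT, calls fn(p, canon, is_rc) where
// canon = min(packed_forward, packed_revcomp) and is_rc indicates the
// reverse complement was the smaller encoding. k <= 25 (2k bits in uint64,
// values stay exactly representable as doubles for k <= 26).
template <typename F>
static inline void for_each_canonical_kmer(const std::string& seq, int k, F fn) {
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  const int shift_rc = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int valid = 0;
  const int n = (int)seq.size();
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift_rc);
    if (++valid >= k) {
      int p = i - k + 1;
      if (fwd <= rc) fn(p, fwd, false); else fn(p, rc, true);
    }
  }
}

#endif
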