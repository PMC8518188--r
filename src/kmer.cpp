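#include "seq_utils.h"
using namespace Rcpp;

// Canonical tetranucleotide index: 256 packed 4-mers collapse onto 136
// canonical keys (4-mer vs its reverse complement counted together).
static std::vector<int> tnf_index_table() {
  std::vector<int> canon(256), idx(256, -1);
  for (int code = 0; code < 256; ++code) {
    int rc = 0;
    for (int j = 0; j < 4; ++j) {
      int b = (code >> (2 * j)) & 3;       // base j from the right = last base first
      rc = (rc << 2) | (3 - b);
    }
    // rc above reverses order while complementing: base order of rc is
    // complement of code read right-to-left, which is the reverse complement.
    canon[code] = std::min(code, rc);
  }
  int next = 0;
  std::vector<int> canon_id(256, -1);
  for (int code = 0; code < 256; ++code) {
    int c = canon[code];
    if (canon_id[c] < 0) canon_id[c] = next++;
    idx[code] = canon_id[c];
  }
  return idx; // next == 136
}

// [[Rcpp::export]]
NumericVector cpp_tnf(std::string seq) {
  static std::vector<int> idx = tnf_index_table();
  NumericVector out(136);
  const int n = (int)seq.size();
  int code = 0, valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | c) & 255;
    if (++valid >= 4) out[idx[code]] += 1.0;
  }
  return out;
}

// Canonical 4-mer string labels in the same order cpp_tnf uses.
// [[Rcpp::export]]
CharacterVector cpp_tnf_labels() {
  static std::vector<int> idx = tnf_index_table();
  CharacterVector out(136);
  std::vector<bool> seen(136, false);
  for (int code = 0; code < 256; ++code) {
    int id = idx[code];
    if (seen[id]) continue;
    int canon = code;
    { // recompute canonical representative
      int rc = 0;
      for (int j = 0; j < 4; ++j) rc = (rc << 2) | (3 - ((code >> (2 * j)) & 3));
      canon = std::min(code, rc);
    }
    if (canon != code) continue; // label with the canonical form only
    std::string s(4, 'A');
    for (int j = 0; j < 4; ++j) s[j] = CODE2BASE[(canon >> (2 * (3 - j))) & 3];
    out[id] = s;
    seen[id] = true;
  }
  return out;
}

// All canonical packed k-mer values of seq in position order (N windows
// skipped). Values are exact in doubles for k <= 26.
// [[Rcpp::export]]
NumericVector cpp_canon_kmers(std::string seq, int k) {
  if (k < 1 || k > 25) stop("k must be in 1..25");
  std::vector<double> vals;
  vals.reserve(seq.size());
  for_each_canonical_kmer(seq, k, [&](int, uint64_t canon, bool) {
    vals.push_back((double)canon);
  });
  return wrap(vals);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp_str(as<std::string>(seqs[i]));
  return out;
}

// Inject i.i.d. per-base errors using R's RNG (deterministic under set.seed).
// At each template base: substitution with prob sub, single-base insertion
// after the base with prob ins, deletion with prob del.
// [[Rcpp::export]]
List cpp_mutate_seqs(CharacterVector seqs, double sub, double ins, double del) {
  RNGScope scope;
  int n = seqs.size();
  CharacterVector out(n);
  IntegerVector nsub(n), nins(n), ndel(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string o;
    o.reserve(s.size() + (size_t)(s.size() * (ins + 0.01)) + 16);
    int cs = 0, ci = 0, cd = 0;
    for (size_t j = 0; j < s.size(); ++j) {
      double u = unif_rand();
      if (u < del) { ++cd; continue; }
      int c = base_code(s[j]);
      if (c < 0) { o.push_back('N'); continue; }
      if (u < del + sub) {
        int alt = (c + 1 + (int)(unif_rand() * 3.0)) & 3;
        o.push_back(CODE2BASE[alt]);
        ++cs;
      } else {
        o.push_back(s[j]);
      }
      if (u >= del + sub && u < del + sub + ins) {
        o.push_back(CODE2BASE[(int)(unif_rand() * 4.0) & 3]);
        ++ci;
      }
    }
    out[i] = o;
    nsub[i] = cs; nins[i] = ci; ndel[i] = cd;
  }
  return List::create(_["seq"] = out, _["n_sub"] = nsub,
                      _["n_ins"] = nins, _["n_del"] = ndel);
}

// Substitution-only short-read error model with per-base qualities: each base
// is assigned quality q_lo with probability p_lo (else q_hi) and then
// substituted with the error probability implied by its own Phred score, so
// emitted qualities are consistent with the realized error rate.
// [[Rcpp::export]]
List cpp_short_read_errors(CharacterVector seqs, int q_hi, int q_lo, double p_lo) {
  RNGScope scope;
  int n = seqs.size();
  CharacterVector out(n), quals(n);
  IntegerVector nsub(n);
  const double e_hi = std::pow(10.0, -q_hi / 10.0);
  const double e_lo = std::pow(10.0, -q_lo / 10.0);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q(s.size(), (char)(33 + q_hi));
    int cs = 0;
    for (size_t j = 0; j < s.size(); ++j) {
      double e = e_hi;
      if (unif_rand() < p_lo) { q[j] = (char)(33 + q_lo); e = e_lo; }
      int c = base_code(s[j]);
      if (c >= 0 && unif_rand() < e) {
        s[j] = CODE2BASE[(c + 1 + (int)(unif_rand() * 3.0)) & 3];
        ++cs;
      }
    }
    out[i] = s; quals[i] = q; nsub[i] = cs;
  }
  return List::create(_["seq"] = out, _["qual"] = quals, _["n_sub"] = nsub);
}

// First-order Markov DNA generator (R RNG): row-stochastic 4x4 transition
// matrix P and initial distribution p0 over A,C,G,T.
// [[Rcpp::export]]
std::string cpp_markov_dna(int n, NumericMatrix P, NumericVector p0) {
  RNGScope scope;
  std::string s(n, 'A');
  if (n <= 0) return s;
  auto draw = [](const double* p) {
    double u = unif_rand(), c = 0;
    for (int b = 0; b < 4; ++b) { c += p[b]; if (u < c) return b; }
    return 3;
  };
  double row[4];
  for (int b = 0; b < 4; ++b) row[b] = p0[b];
  int cur = draw(row);
  s[0] = CODE2BASE[cur];
  for (int i = 1; i < n; ++i) {
    for (int b = 0; b < 4; ++b) row[b] = P(cur, b);
    cur = draw(row);
    s[i] = CODE2BASE[cur];
  }
  return s;
}
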