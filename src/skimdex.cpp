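// Core sequence / Bloom-filter machinery.
//
// Everything here operates on canonical s-mers and k-mers: the lexicographic
// minimum of a window and its reverse complement.  s-mers of length <= 32 are
// packed two bits per base into a uint64_t (A=0 < C=1 < G=2 < T=3 preserves
// lexicographic order), longer windows fall back to std::string.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <cstring>
#include <string>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

namespace {

const char BASES[4] = {'A', 'C', 'G', 'T'};

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char comp_char(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

inline uint64_t fmix64(uint64_t h) {
  h ^= h >> 33;
  h *= 0xff51afd7ed558ccdULL;
  h ^= h >> 33;
  h *= 0xc4ceb9fe1a85ec53ULL;
  h ^= h >> 33;
  return h;
}

// seeded hash of a packed canonical s-mer
inline uint64_t hash_packed(uint64_t v, int len, uint64_t seed) {
  return fmix64(v ^ (seed * 0x9E3779B97F4A7C15ULL) ^
                ((uint64_t)len * 0xA24BAED4963EE407ULL));
}

// seeded FNV-1a + finalizer for windows longer than 32 bases
inline uint64_t hash_string(const std::string& s, uint64_t seed) {
  uint64_t h = 14695981039346656037ULL;
  for (char c : s) {
    h ^= (uint64_t)(unsigned char)c;
    h *= 1099511628211ULL;
  }
  return fmix64(h ^ (seed * 0x9E3779B97F4A7C15ULL));
}

// Canonical packed value of every length-`len` window of s (len <= 32).
// ok[i] = 0 when the window contains a non-ACGT character.
void packed_windows(const char* s, R_xlen_t L, int len,
                    std::vector<uint64_t>& out, std::vector<char>& ok) {
  R_xlen_t n = (L >= len) ? (L - len + 1) : 0;
  out.assign(n, 0);
  ok.assign(n, 0);
  if (n == 0) return;
  const uint64_t mask = (len == 32) ? ~0ULL : ((1ULL << (2 * len)) - 1);
  const int shift = 2 * (len - 1);
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  for (R_xlen_t j = 0; j < L; ++j) {
    int c = base_code(s[j]);
    if (c < 0) { run = 0; c = 0; } else { ++run; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
    if (j >= (R_xlen_t)len - 1) {
      R_xlen_t i = j - len + 1;
      if (run >= len) {
        ok[i] = 1;
        out[i] = fwd < rc ? fwd : rc;
      }
    }
  }
}

// valid-window flags only (used by the string path)
void window_validity(const char* s, R_xlen_t L, int len, std::vector<char>& ok) {
  R_xlen_t n = (L >= len) ? (L - len + 1) : 0;
  ok.assign(n, 0);
  int run = 0;
  for (R_xlen_t j = 0; j < L; ++j) {
    if (base_code(s[j]) < 0) run = 0; else ++run;
    if (j >= (R_xlen_t)len - 1 && run >= len) ok[j - len + 1] = 1;
  }
}

// canonical string form of a valid window
void canonical_window(const char* p, int len, std::string& out) {
  bool fwd = true;
  for (int i = 0; i < len; ++i) {
    char f = (char)toupper(p[i]);
    char r = comp_char(p[len - 1 - i]);
    if (f < r) { fwd = true; break; }
    if (f > r) { fwd = false; break; }
  }
  out.resize(len);
  if (fwd) {
    for (int i = 0; i < len; ++i) out[i] = (char)toupper(p[i]);
  } else {
    for (int i = 0; i < len; ++i) out[i] = comp_char(p[len - 1 - i]);
  }
}

std::string unpack_kmer(uint64_t v, int len) {
  std::string s((size_t)len, 'A');
  for (int i = len - 1; i >= 0; --i) {
    s[(size_t)i] = BASES[v & 3ULL];
    v >>= 2;
  }
  return s;
}

// canonicalize one window given as a C string; false when it has non-ACGT
bool canon_packed_one(const char* s, int len, uint64_t& out) {
  uint64_t fwd = 0, rc = 0;
  const int shift = 2 * (len - 1);
  for (int i = 0; i < len; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    fwd = (fwd << 2) | (uint64_t)c;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
  }
  out = fwd < rc ? fwd : rc;
  return true;
}

bool canon_string_one(const char* s, int len, std::string& out) {
  for (int i = 0; i < len; ++i)
    if (base_code(s[i]) < 0) return false;
  canonical_window(s, len, out);
  return true;
}

// ---- containers ------------------------------------------------------------

struct SmerSet {
  int len;
  std::unordered_set<uint64_t> pset;
  std::unordered_set<std::string> sset;
  explicit SmerSet(int len_) : len(len_) {}
  bool packed() const { return len <= 32; }
  double size() const {
    return packed() ? (double)pset.size() : (double)sset.size();
  }
};

struct BloomBits {
  uint64_t m;
  uint64_t seed;
  int len;
  double n_inserted;
  std::vector<uint64_t> w;
  BloomBits(double m_, double seed_, int len_)
      : m((uint64_t)m_), seed((uint64_t)seed_), len(len_), n_inserted(0),
        w((size_t)(((uint64_t)m_ + 63) / 64), 0ULL) {}
  inline void set(uint64_t h) {
    if (m == 0) return;
    uint64_t b = h % m;
    w[b >> 6] |= (1ULL << (b & 63));
  }
  inline bool get(uint64_t h) const {
    if (m == 0) return false;
    uint64_t b = h % m;
    return (w[b >> 6] >> (b & 63)) & 1ULL;
  }
};

inline SmerSet* as_set(SEXP p) {
  XPtr<SmerSet> x(p);
  return x.get();
}
inline BloomBits* as_bloom(SEXP p) {
  XPtr<BloomBits> x(p);
  return x.get();
}

// membership of every s-window of one sequence against either backend
void window_membership(const char* s, R_xlen_t L, int slen,
                       const BloomBits* bf, const SmerSet* es,
                       std::vector<char>& member,
                       std::vector<uint64_t>& pw, std::vector<char>& ok,
                       std::vector<char>& okbuf) {
  R_xlen_t n = (L >= slen) ? (L - slen + 1) : 0;
  member.assign(n, 0);
  if (n == 0) return;
  if (slen <= 32) {
    packed_windows(s, L, slen, pw, ok);
    for (R_xlen_t i = 0; i < n; ++i) {
      if (!ok[i]) continue;
      if (es != nullptr)
        member[i] = es->pset.count(pw[i]) ? 1 : 0;
      else
        member[i] = bf->get(hash_packed(pw[i], slen, bf->seed)) ? 1 : 0;
    }
  } else {
    window_validity(s, L, slen, okbuf);
    std::string buf;
    for (R_xlen_t i = 0; i < n; ++i) {
      if (!okbuf[i]) continue;
      canonical_window(s + i, slen, buf);
      if (es != nullptr)
        member[i] = es->sset.count(buf) ? 1 : 0;
      else
        member[i] = bf->get(hash_string(buf, bf->seed)) ? 1 : 0;
    }
  }
}

}  // namespace

// ---- s-mer sets ------------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_smer_set(CharacterVector seqs, int s) {
  if (s < 1) stop("s-mer length must be >= 1");
  XPtr<SmerSet> p(new SmerSet(s), true);
  std::vector<uint64_t> pw;
  std::vector<char> ok;
  std::string buf;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (seqs[i] == NA_STRING) continue;
    const char* str = CHAR(seqs[i]);
    R_xlen_t L = LENGTH(seqs[i]);
    if (p->packed()) {
      packed_windows(str, L, s, pw, ok);
      for (R_xlen_t j = 0; j < (R_xlen_t)pw.size(); ++j)
        if (ok[j]) p->pset.insert(pw[j]);
    } else {
      window_validity(str, L, s, ok);
      for (R_xlen_t j = 0; j < (R_xlen_t)ok.size(); ++j) {
        if (!ok[j]) continue;
        canonical_window(str + j, s, buf);
        p->sset.insert(buf);
      }
    }
  }
  return p;
}

// [[Rcpp::export]]
SEXP cpp_smer_set_empty(int s) {
  if (s < 1) stop("s-mer length must be >= 1");
  XPtr<SmerSet> p(new SmerSet(s), true);
  return p;
}

// [[Rcpp::export]]
double cpp_smer_set_insert(SEXP ptr, CharacterVector smers) {
  SmerSet* p = as_set(ptr);
  double novel = 0;
  uint64_t v;
  std::string buf;
  for (R_xlen_t i = 0; i < smers.size(); ++i) {
    if (smers[i] == NA_STRING) stop("NA s-mer");
    const char* s = CHAR(smers[i]);
    int L = LENGTH(smers[i]);
    if (L != p->len)
      stop("s-mer has length %d; this set stores s-mers of length %d", L, p->len);
    if (p->packed()) {
      if (!canon_packed_one(s, p->len, v)) stop("ambiguous base in s-mer");
      if (p->pset.insert(v).second) novel += 1;
    } else {
      if (!canon_string_one(s, p->len, buf)) stop("ambiguous base in s-mer");
      if (p->sset.insert(buf).second) novel += 1;
    }
  }
  return novel;
}

// [[Rcpp::export]]
double cpp_smer_set_size(SEXP ptr) { return as_set(ptr)->size(); }

// [[Rcpp::export]]
int cpp_smer_set_len(SEXP ptr) { return as_set(ptr)->len; }

// [[Rcpp::export]]
LogicalVector cpp_smer_set_contains(SEXP ptr, CharacterVector smers) {
  SmerSet* p = as_set(ptr);
  LogicalVector out(smers.size());
  uint64_t v;
  std::string buf;
  for (R_xlen_t i = 0; i < smers.size(); ++i) {
    if (smers[i] == NA_STRING) { out[i] = false; continue; }
    const char* s = CHAR(smers[i]);
    int L = LENGTH(smers[i]);
    if (L != p->len)
      stop("s-mer has length %d; this set stores s-mers of length %d", L, p->len);
    if (p->packed()) {
      out[i] = canon_packed_one(s, p->len, v) && p->pset.count(v) > 0;
    } else {
      out[i] = canon_string_one(s, p->len, buf) && p->sset.count(buf) > 0;
    }
  }
  return out;
}

// sorted canonical elements (deterministic order, used for serialization)
// [[Rcpp::export]]
CharacterVector cpp_smer_set_elements(SEXP ptr) {
  SmerSet* p = as_set(ptr);
  if (p->packed()) {
    std::vector<uint64_t> v(p->pset.begin(), p->pset.end());
    std::sort(v.begin(), v.end());
    CharacterVector out(v.size());
    for (size_t i = 0; i < v.size(); ++i)
      out[(R_xlen_t)i] = unpack_kmer(v[i], p->len);
    return out;
  }
  std::vector<std::string> v(p->sset.begin(), p->sset.end());
  std::sort(v.begin(), v.end());
  return wrap(v);
}

// number of valid s-windows of each sequence that are members of the set
// [[Rcpp::export]]
IntegerVector cpp_count_member_smers(CharacterVector seqs, SEXP ptr) {
  SmerSet* p = as_set(ptr);
  IntegerVector out(seqs.size());
  std::vector<char> member;
  std::vector<uint64_t> pw;
  std::vector<char> ok, okbuf;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (seqs[i] == NA_STRING) { out[i] = 0; continue; }
    window_membership(CHAR(seqs[i]), LENGTH(seqs[i]), p->len, nullptr, p,
                      member, pw, ok, okbuf);
    int cnt = 0;
    for (char m : member) cnt += m;
    out[i] = cnt;
  }
  return out;
}

// ---- Bloom filters ---------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_bloom_new(double m, double seed, int len) {
  if (m < 0) stop("m must be >= 0");
  if (len < 1) stop("s-mer length must be >= 1");
  XPtr<BloomBits> p(new BloomBits(m, seed, len), true);
  return p;
}

// [[Rcpp::export]]
void cpp_bloom_insert_set(SEXP bptr, SEXP sptr) {
  BloomBits* b = as_bloom(bptr);
  SmerSet* p = as_set(sptr);
  if (p->len != b->len)
    stop("s-mer length mismatch between set (%d) and filter (%d)", p->len, b->len);
  if (p->packed()) {
    for (uint64_t v : p->pset) b->set(hash_packed(v, b->len, b->seed));
  } else {
    for (const std::string& s : p->sset) b->set(hash_string(s, b->seed));
  }
  b->n_inserted += p->size();
}

// [[Rcpp::export]]
double cpp_bloom_insert_smers(SEXP bptr, CharacterVector smers) {
  BloomBits* b = as_bloom(bptr);
  uint64_t v;
  std::string buf;
  for (R_xlen_t i = 0; i < smers.size(); ++i) {
    if (smers[i] == NA_STRING) stop("NA s-mer");
    const char* s = CHAR(smers[i]);
    int L = LENGTH(smers[i]);
    if (L != b->len)
      stop("s-mer has length %d; this filter stores s-mers of length %d", L, b->len);
    if (b->len <= 32) {
      if (!canon_packed_one(s, b->len, v)) stop("ambiguous base in s-mer");
      b->set(hash_packed(v, b->len, b->seed));
    } else {
      if (!canon_string_one(s, b->len, buf)) stop("ambiguous base in s-mer");
      b->set(hash_string(buf, b->seed));
    }
  }
  b->n_inserted += (double)smers.size();
  return b->n_inserted;
}

// [[Rcpp::export]]
LogicalVector cpp_bloom_contains(SEXP bptr, CharacterVector smers) {
  BloomBits* b = as_bloom(bptr);
  LogicalVector out(smers.size());
  uint64_t v;
  std::string buf;
  for (R_xlen_t i = 0; i < smers.size(); ++i) {
    if (smers[i] == NA_STRING) { out[i] = false; continue; }
    const char* s = CHAR(smers[i]);
    int L = LENGTH(smers[i]);
    if (L != b->len)
      stop("s-mer has length %d; this filter stores s-mers of length %d", L, b->len);
    if (b->len <= 32) {
      out[i] = canon_packed_one(s, b->len, v) &&
               b->get(hash_packed(v, b->len, b->seed));
    } else {
      out[i] = canon_string_one(s, b->len, buf) &&
               b->get(hash_string(buf, b->seed));
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_bloom_info(SEXP bptr) {
  BloomBits* b = as_bloom(bptr);
  return List::create(_["m"] = (double)b->m, _["n_inserted"] = b->n_inserted,
                      _["seed"] = (double)b->seed, _["s"] = b->len);
}

// [[Rcpp::export]]
RawVector cpp_bloom_bits(SEXP bptr) {
  BloomBits* b = as_bloom(bptr);
  RawVector out((R_xlen_t)(b->w.size() * 8));
  if (!b->w.empty())
    std::memcpy(RAW(out), b->w.data(), b->w.size() * 8);
  return out;
}

// [[Rcpp::export]]
SEXP cpp_bloom_from_bits(RawVector bits, double m, double seed, double n, int len) {
  XPtr<BloomBits> p(new BloomBits(m, seed, len), true);
  if ((size_t)bits.size() != p->w.size() * 8)
    stop("bit-field payload does not match m");
  if (!p->w.empty())
    std::memcpy(p->w.data(), RAW(bits), p->w.size() * 8);
  p->n_inserted = n;
  return p;
}

// ---- k-mer extraction and findere queries ----------------------------------

// [[Rcpp::export]]
CharacterVector cpp_canonical_kmers(std::string seq, int len) {
  if (len < 1) stop("k-mer length must be >= 1");
  const char* s = seq.c_str();
  R_xlen_t L = (R_xlen_t)seq.size();
  std::vector<std::string> out;
  if (L >= len) out.reserve((size_t)(L - len + 1));
  if (len <= 32) {
    std::vector<uint64_t> pw;
    std::vector<char> ok;
    packed_windows(s, L, len, pw, ok);
    for (R_xlen_t i = 0; i < (R_xlen_t)pw.size(); ++i)
      if (ok[i]) out.push_back(unpack_kmer(pw[i], len));
  } else {
    std::vector<char> ok;
    window_validity(s, L, len, ok);
    std::string buf;
    for (R_xlen_t i = 0; i < (R_xlen_t)ok.size(); ++i) {
      if (!ok[i]) continue;
      canonical_window(s + i, len, buf);
      out.push_back(buf);
    }
  }
  return wrap(out);
}

// [[Rcpp::export]]
CharacterVector cpp_canonicalize(CharacterVector x) {
  CharacterVector out(x.size());
  uint64_t v;
  std::string buf;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char* s = CHAR(x[i]);
    int L = LENGTH(x[i]);
    if (L == 0) { out[i] = NA_STRING; continue; }
    if (L <= 32) {
      if (canon_packed_one(s, L, v)) out[i] = unpack_kmer(v, L);
      else out[i] = NA_STRING;
    } else {
      if (canon_string_one(s, L, buf)) out[i] = buf;
      else out[i] = NA_STRING;
    }
  }
  return out;
}

// S_G for each read: number of k-windows whose z constituent s-mers
// (s = k - z + 1) are all members of the filter / set.
// [[Rcpp::export]]
IntegerVector cpp_count_shared(CharacterVector reads, SEXP ptr, bool exact,
                               int k, int z) {
  if (z < 1 || z >= k) stop("need 1 <= z < k");
  const int slen = k - z + 1;
  SmerSet* es = exact ? as_set(ptr) : nullptr;
  BloomBits* bf = exact ? nullptr : as_bloom(ptr);
  const int have = exact ? es->len : bf->len;
  if (have != slen)
    stop("filter stores s-mers of length %d but k - z + 1 = %d", have, slen);
  IntegerVector out(reads.size());
  std::vector<char> member;
  std::vector<uint64_t> pw;
  std::vector<char> ok, okbuf;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    if (reads[i] == NA_STRING) { out[i] = 0; continue; }
    const char* s = CHAR(reads[i]);
    R_xlen_t L = LENGTH(reads[i]);
    R_xlen_t nk = (L >= k) ? (L - k + 1) : 0;
    if (nk == 0) { out[i] = 0; continue; }
    window_membership(s, L, slen, bf, es, member, pw, ok, okbuf);
    int cnt = 0;
    for (R_xlen_t j = 0; j < nk; ++j) {
      bool all = true;
      for (int t = 0; t < z; ++t)
        if (!member[j + t]) { all = false; break; }
      if (all) ++cnt;
    }
    out[i] = cnt;
  }
  return out;
}

// findere verdict for individual k-mers (each string must have length k)
// [[Rcpp::export]]
LogicalVector cpp_query_kmers(CharacterVector kmers, SEXP ptr, bool exact,
                              int k, int z) {
  if (z < 1 || z >= k) stop("need 1 <= z < k");
  const int slen = k - z + 1;
  SmerSet* es = exact ? as_set(ptr) : nullptr;
  BloomBits* bf = exact ? nullptr : as_bloom(ptr);
  const int have = exact ? es->len : bf->len;
  if (have != slen)
    stop("filter stores s-mers of length %d but k - z + 1 = %d", have, slen);
  LogicalVector out(kmers.size());
  std::vector<char> member;
  std::vector<uint64_t> pw;
  std::vector<char> ok, okbuf;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    if (kmers[i] == NA_STRING) { out[i] = false; continue; }
    R_xlen_t L = LENGTH(kmers[i]);
    if (L != k) stop("k-mer has length %d; expected k = %d", (int)L, k);
    window_membership(CHAR(kmers[i]), L, slen, bf, es, member, pw, ok, okbuf);
    bool all = true;
    for (char m : member)
      if (!m) { all = false; break; }
    out[i] = all && !member.empty();
  }
  return out;
}

// ---- distinct-count estimator ----------------------------------------------

// One-in-2^b hash-sampled distinct canonical s-mer estimate.
// [[Rcpp::export]]
double cpp_distinct_estimate(CharacterVector seqs, int s, int sample_bits) {
  if (s < 1) stop("s-mer length must be >= 1");
  if (sample_bits < 0 || sample_bits > 32) stop("sample_bits must be in [0, 32]");
  const uint64_t SEED0 = 0x5EEDBA5Eu;
  std::unordered_set<uint64_t> sampled;
  std::vector<uint64_t> pw;
  std::vector<char> ok;
  std::string buf;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (seqs[i] == NA_STRING) continue;
    const char* str = CHAR(seqs[i]);
    R_xlen_t L = LENGTH(seqs[i]);
    if (s <= 32) {
      packed_windows(str, L, s, pw, ok);
      for (R_xlen_t j = 0; j < (R_xlen_t)pw.size(); ++j) {
        if (!ok[j]) continue;
        uint64_t h = hash_packed(pw[j], s, SEED0);
        if (sample_bits == 0 || (h >> (64 - sample_bits)) == 0)
          sampled.insert(pw[j]);
      }
    } else {
      window_validity(str, L, s, ok);
      for (R_xlen_t j = 0; j < (R_xlen_t)ok.size(); ++j) {
        if (!ok[j]) continue;
        canonical_window(str + j, s, buf);
        uint64_t h = hash_string(buf, SEED0);
        if (sample_bits == 0 || (h >> (64 - sample_bits)) == 0)
          sampled.insert(h);
      }
    }
  }
  return (double)sampled.size() * std::pow(2.0, sample_bits);
}

// ---- simulators (all randomness through R's RNG) ---------------------------

// [[Rcpp::export]]
String cpp_simulate_genome(double size) {
  if (size < 1) stop("genome size must be >= 1");
  size_t n = (size_t)size;
  std::string g(n, 'A');
  for (size_t i = 0; i < n; ++i) {
    int b = (int)(unif_rand() * 4.0);
    if (b > 3) b = 3;
    g[i] = BASES[b];
  }
  return String(g);
}

// [[Rcpp::export]]
CharacterVector cpp_random_kmers(double n, int len) {
  if (len < 1) stop("k-mer length must be >= 1");
  R_xlen_t nn = (R_xlen_t)n;
  CharacterVector out(nn);
  std::string buf((size_t)len, 'A');
  for (R_xlen_t i = 0; i < nn; ++i) {
    for (int j = 0; j < len; ++j) {
      int b = (int)(unif_rand() * 4.0);
      if (b > 3) b = 3;
      buf[(size_t)j] = BASES[b];
    }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_extract_reads(CharacterVector genome, IntegerVector starts,
                                  IntegerVector lens, LogicalVector rc) {
  if (genome.size() != 1) stop("expected a single genome sequence");
  const char* g = CHAR(genome[0]);
  R_xlen_t G = LENGTH(genome[0]);
  R_xlen_t n = starts.size();
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    int st = starts[i];
    int L = lens[lens.size() == 1 ? 0 : i];
    if (st < 1 || (R_xlen_t)st + L - 1 > G) stop("read extends past genome end");
    buf.assign(g + st - 1, (size_t)L);
    if (rc[rc.size() == 1 ? 0 : i]) {
      std::string r((size_t)L, 'N');
      for (int j = 0; j < L; ++j) r[(size_t)j] = comp_char(buf[(size_t)(L - 1 - j)]);
      buf = r;
    }
    out[i] = buf;
  }
  return out;
}

// iid per-base substitution errors at `rate`
// [[Rcpp::export]]
CharacterVector cpp_mutate_seqs(CharacterVector seqs, double rate) {
  if (rate < 0 || rate > 1) stop("error rate must be in [0, 1]");
  CharacterVector out(seqs.size());
  std::string buf;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    buf.assign(CHAR(seqs[i]), (size_t)LENGTH(seqs[i]));
    if (rate > 0) {
      for (size_t j = 0; j < buf.size(); ++j) {
        int c = base_code(buf[j]);
        if (c < 0) continue;
        if (unif_rand() < rate) {
          int off = 1 + (int)(unif_rand() * 3.0);
          if (off > 3) off = 3;
          buf[j] = BASES[(c + off) & 3];
        }
      }
    }
    out[i] = buf;
  }
  return out;
}

// terminal deamination: C->T with probability p5 * decay^d5 from the 5' end,
// G->A with the same law from the 3' end (double-stranded damage pattern)
// [[Rcpp::export]]
CharacterVector cpp_deaminate(CharacterVector seqs, double p5, double decay) {
  if (p5 < 0 || p5 > 1) stop("deamination rate must be in [0, 1]");
  if (decay < 0 || decay > 1) stop("decay must be in [0, 1]");
  CharacterVector out(seqs.size());
  std::string buf;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    buf.assign(CHAR(seqs[i]), (size_t)LENGTH(seqs[i]));
    size_t L = buf.size();
    if (p5 > 0) {
      double p = p5;
      for (size_t j = 0; j < L; ++j) {  // 5' -> 3'
        if (buf[j] == 'C' || buf[j] == 'c')
          if (unif_rand() < p) buf[j] = 'T';
        p *= decay;
        if (p < 1e-12) break;
      }
      p = p5;
      for (size_t j = L; j-- > 0;) {  // 3' -> 5'
        if (buf[j] == 'G' || buf[j] == 'g')
          if (unif_rand() < p) buf[j] = 'A';
        p *= decay;
        if (p < 1e-12) break;
      }
    }
    out[i] = buf;
  }
  return out;
}
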