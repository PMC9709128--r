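#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <set>
using namespace Rcpp;

// ---- hashing primitives ----------------------------------------------------
//
// The hash family must be a pure function of (key, seed, m) so that an index
// serialized on one machine classifies identically everywhere.  Keys are
// 2-bit packed (A=0, C=1, G=2, T=3, 32 bases per 64-bit word) and mixed with
// a splitmix64 finalizer, once per word plus a final length fold.

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static inline char base_comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string rc(s.rbegin(), s.rend());
  for (size_t i = 0; i < rc.size(); ++i) rc[i] = base_comp(rc[i]);
  return rc;
}

// lexicographic min of a k-mer and its reverse complement
static std::string canonical_str(const std::string& s) {
  std::string rc = revcomp_str(s);
  return (rc < s) ? rc : s;
}

static uint64_t hash_one(const std::string& key, uint64_t seed, uint64_t m) {
  uint64_t h = splitmix64(seed ^ 0x51ED270B9F9B5C41ULL);
  uint64_t w = 0;
  int nb = 0;
  uint64_t j = 0;
  for (size_t i = 0; i < key.size(); ++i) {
    int c = base_code(key[i]);
    if (c < 0) stop("k-mer contains a character outside {A,C,G,T}: '%s'", key.c_str());
    w = (w << 2) | (uint64_t)c;
    if (++nb == 32) {
      h = splitmix64(h ^ w ^ ((j + 1) * 0x9E3779B97F4A7C15ULL));
      w = 0; nb = 0; ++j;
    }
  }
  if (nb > 0) h = splitmix64(h ^ w ^ ((j + 1) * 0x9E3779B97F4A7C15ULL));
  h = splitmix64(h ^ (uint64_t)key.size());
  return h % m;
}

static std::vector<uint64_t> seeds_from(const NumericVector& seeds) {
  std::vector<uint64_t> sd(seeds.size());
  for (int i = 0; i < seeds.size(); ++i) sd[i] = (uint64_t)seeds[i];
  return sd;
}

// Derive n pairwise-distinct 31-bit seeds from one master seed.
// [[Rcpp::export]]
NumericVector cpp_derive_seeds(double master_seed, int n) {
  uint64_t st = (uint64_t)master_seed;
  std::set<uint64_t> used;
  NumericVector out(n);
  int i = 0;
  while (i < n) {
    st = splitmix64(st);
    uint64_t s = st >> 33;           // 31-bit: exactly representable in R
    if (s == 0 || used.count(s)) continue;
    used.insert(s);
    out[i++] = (double)s;
  }
  return out;
}

// Hash a vector of keys with every seed; returns an n x N matrix of positions.
// [[Rcpp::export]]
NumericMatrix cpp_hash_kmers(CharacterVector keys, NumericVector seeds, double m) {
  if (m < 1) stop("m must be >= 1");
  uint64_t M = (uint64_t)m;
  std::vector<uint64_t> sd = seeds_from(seeds);
  NumericMatrix out(seeds.size(), keys.size());
  for (int j = 0; j < keys.size(); ++j) {
    std::string key = as<std::string>(keys[j]);
    for (int i = 0; i < (int)sd.size(); ++i)
      out(i, j) = (double)hash_one(key, sd[i], M);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical_kmers(CharacterVector keys) {
  CharacterVector out(keys.size());
  for (int i = 0; i < keys.size(); ++i) {
    std::string s = as<std::string>(keys[i]);
    for (size_t j = 0; j < s.size(); ++j) {
      if (base_code(s[j]) < 0)
        stop("k-mer contains a character outside {A,C,G,T}: '%s'", s.c_str());
    }
    out[i] = canonical_str(s);
  }
  return out;
}

// prefix[i] = number of non-ACGT characters in seq[0..i)
static std::vector<int> invalid_prefix(const std::string& seq) {
  std::vector<int> pre(seq.size() + 1, 0);
  for (size_t i = 0; i < seq.size(); ++i)
    pre[i + 1] = pre[i] + (base_code(seq[i]) < 0 ? 1 : 0);
  return pre;
}

// All valid k-mer windows of a sequence, 0-based start positions; windows
// containing any non-ACGT character are skipped.
// [[Rcpp::export]]
List cpp_extract_kmers(std::string seq, int k, bool canonical) {
  if (k < 1) stop("k must be >= 1");
  std::vector<int> pos;
  std::vector<std::string> km;
  if ((int)seq.size() >= k) {
    std::vector<int> pre = invalid_prefix(seq);
    for (int p = 0; p + k <= (int)seq.size(); ++p) {
      if (pre[p + k] - pre[p] != 0) continue;
      std::string w = seq.substr(p, k);
      pos.push_back(p);
      km.push_back(canonical ? canonical_str(w) : w);
    }
  }
  return List::create(_["pos"] = wrap(pos), _["kmer"] = wrap(km));
}

// ---- Algorithm 1 / Algorithm 2 --------------------------------------------

static std::vector<int> reduce_core(IntegerVector& F, const std::string& seq,
                                    const std::vector<int>& positions, int gid,
                                    int k, const std::vector<uint64_t>& sd,
                                    uint64_t M, double omega, bool canonical) {
  // Literal transcription of the signature-thinning pass: keep the first
  // position, then a position only when it exceeds (last kept + omega);
  // dropped positions have all their hash entries dirtied DURING the scan,
  // kept positions are re-stamped to gid AFTER the scan.  The dirty-then-
  // restamp order is semantically significant and is preserved as published.
  std::vector<int> selected;
  if (positions.empty()) return selected;
  selected.push_back(positions[0]);
  long om = (long)omega;
  for (size_t i = 1; i < positions.size(); ++i) {
    if ((long)selected.back() + om < (long)positions[i]) {
      selected.push_back(positions[i]);
    } else {
      std::string x = seq.substr(positions[i], k);
      if (canonical) x = canonical_str(x);
      for (size_t j = 0; j < sd.size(); ++j)
        F[(R_xlen_t)hash_one(x, sd[j], M)] = -1;
    }
  }
  for (size_t i = 0; i < selected.size(); ++i) {
    std::string x = seq.substr(selected[i], k);
    if (canonical) x = canonical_str(x);
    for (size_t j = 0; j < sd.size(); ++j)
      F[(R_xlen_t)hash_one(x, sd[j], M)] = gid;
  }
  return selected;
}

// One pass of the genome-processing algorithm over all contigs of one genome.
// F is modified in place (the caller owns the only reference).  Returns, per
// contig, the collected signature positions (phase 2) and the positions kept
// after the reduce pass (identical when omega == 0 or phase == 1).
// [[Rcpp::export]]
List cpp_process_genome(IntegerVector F, List contigs, int gid, int k,
                        NumericVector seeds, double m, int phase,
                        double omega, bool canonical) {
  if (phase != 1 && phase != 2) stop("phase must be 1 or 2");
  if (k < 1) stop("k must be >= 1");
  uint64_t M = (uint64_t)m;
  std::vector<uint64_t> sd = seeds_from(seeds);
  int n = (int)sd.size();
  List pos_out(contigs.size()), sel_out(contigs.size());
  std::vector<uint64_t> idx(n);
  for (int ci = 0; ci < contigs.size(); ++ci) {
    std::string seq = as<std::string>(contigs[ci]);
    std::vector<int> positions;
    if ((int)seq.size() >= k) {
      std::vector<int> pre = invalid_prefix(seq);
      for (int p = 0; p + k <= (int)seq.size(); ++p) {
        if (pre[p + k] - pre[p] != 0) continue;
        std::string x = seq.substr(p, k);
        if (canonical) x = canonical_str(x);
        bool unique = true;
        for (int i = 0; i < n; ++i) {
          uint64_t v = hash_one(x, sd[i], M);
          idx[i] = v;
          int fv = F[(R_xlen_t)v];
          if (fv != 0 && fv != gid) unique = false;
        }
        if (unique) {
          if (phase == 2) positions.push_back(p);
          for (int i = 0; i < n; ++i) F[(R_xlen_t)idx[i]] = gid;
        } else {
          for (int i = 0; i < n; ++i) F[(R_xlen_t)idx[i]] = -1;
        }
      }
    }
    std::vector<int> selected = positions;
    if (phase == 2 && omega > 0 && !positions.empty())
      selected = reduce_core(F, seq, positions, gid, k, sd, M, omega, canonical);
    pos_out[ci] = wrap(positions);
    sel_out[ci] = wrap(selected);
  }
  return List::create(_["positions"] = pos_out, _["selected"] = sel_out);
}

// Standalone reduce pass on one contig (F modified in place).
// [[Rcpp::export]]
IntegerVector cpp_reduce(IntegerVector F, std::string seq, IntegerVector positions,
                         int gid, int k, NumericVector seeds, double m,
                         double omega, bool canonical) {
  uint64_t M = (uint64_t)m;
  std::vector<uint64_t> sd = seeds_from(seeds);
  std::vector<int> pos(positions.begin(), positions.end());
  std::vector<int> sel = reduce_core(F, seq, pos, gid, k, sd, M, omega, canonical);
  return wrap(sel);
}

// ---- classification --------------------------------------------------------

// Per-k-mer decision: any untouched entry -> absent (0); all n entries equal
// to the same positive id -> that id; anything else (a dirty entry, or
// conflicting ids) -> dirty (-1).
static int classify_one(const IntegerVector& F, const std::string& key,
                        const std::vector<uint64_t>& sd, uint64_t M) {
  int first = 0;
  for (size_t i = 0; i < sd.size(); ++i) {
    int e = F[(R_xlen_t)hash_one(key, sd[i], M)];
    if (e == 0) return 0;
    if (i == 0) first = e;
    else if (e != first) return -1;
  }
  return first > 0 ? first : -1;
}

// [[Rcpp::export]]
IntegerVector cpp_classify_kmers(IntegerVector F, CharacterVector keys,
                                 NumericVector seeds, double m, bool canonical) {
  uint64_t M = (uint64_t)m;
  std::vector<uint64_t> sd = seeds_from(seeds);
  IntegerVector out(keys.size());
  for (int j = 0; j < keys.size(); ++j) {
    std::string key = as<std::string>(keys[j]);
    if (canonical) key = canonical_str(key);
    out[j] = classify_one(F, key, sd, M);
  }
  return out;
}

// Calls for every valid k-mer window of a read, in scan order.
// [[Rcpp::export]]
IntegerVector cpp_classify_sequence(IntegerVector F, std::string seq, int k,
                                    NumericVector seeds, double m, bool canonical) {
  uint64_t M = (uint64_t)m;
  std::vector<uint64_t> sd = seeds_from(seeds);
  std::vector<int> calls;
  if ((int)seq.size() >= k) {
    std::vector<int> pre = invalid_prefix(seq);
    for (int p = 0; p + k <= (int)seq.size(); ++p) {
      if (pre[p + k] - pre[p] != 0) continue;
      std::string x = seq.substr(p, k);
      if (canonical) x = canonical_str(x);
      calls.push_back(classify_one(F, x, sd, M));
    }
  }
  return wrap(calls);
}

// First-hit fast path: stop scanning at the first positive call.
// Returns 0 when no k-mer call is positive.
// [[Rcpp::export]]
int cpp_first_hit(IntegerVector F, std::string seq, int k,
                  NumericVector seeds, double m, bool canonical) {
  uint64_t M = (uint64_t)m;
  std::vector<uint64_t> sd = seeds_from(seeds);
  if ((int)seq.size() < k) return 0;
  std::vector<int> pre = invalid_prefix(seq);
  for (int p = 0; p + k <= (int)seq.size(); ++p) {
    if (pre[p + k] - pre[p] != 0) continue;
    std::string x = seq.substr(p, k);
    if (canonical) x = canonical_str(x);
    int c = classify_one(F, x, sd, M);
    if (c > 0) return c;
  }
  return 0;
}

// ---- CRC-32 (IEEE 802.3 polynomial) for the index file checksum ------------

// [[Rcpp::export]]
double cpp_crc32(RawVector bytes) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int j = 0; j < 8; ++j)
        c = (c & 1) ? (0xEDB88320U ^ (c >> 1)) : (c >> 1);
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFU;
  for (R_xlen_t i = 0; i < bytes.size(); ++i)
    crc = table[(crc ^ bytes[i]) & 0xFFU] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFU);
}
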