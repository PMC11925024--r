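#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static inline char complement(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = complement(c);
  return r;
}

static std::string decode_kmer(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BITS2BASE[code & 3ULL];
    code >>= 2;
  }
  return s;
}

// Count k-mers over a set of sequences.  Windows containing non-ACGT bases
// are skipped.  For k <= 32 a rolling 2-bit encoding is used (A<C<G<T maps
// to 0<1<2<3, so numeric order on codes equals lexicographic order on
// strings of equal length); longer k falls back to explicit strings.
// [[Rcpp::export]]
IntegerVector cpp_count_kmers(CharacterVector seqs, int k, bool canonical) {
  if (k < 1) stop("k must be >= 1");
  if (k <= 32) {
    std::unordered_map<uint64_t, double> tab;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
    const int shift_rc = 2 * (k - 1);
    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
      const char* str = CHAR(STRING_ELT(seqs, s));
      int n = LENGTH(STRING_ELT(seqs, s));
      uint64_t fwd = 0, rc = 0;
      int run = 0;
      for (int i = 0; i < n; ++i) {
        int b = base2bits(str[i]);
        if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rc = (rc >> 2) | ((uint64_t)(3 - b) << shift_rc);
        if (++run >= k) {
          uint64_t key = canonical ? std::min(fwd, rc) : fwd;
          tab[key] += 1.0;
        }
      }
    }
    std::vector<std::pair<uint64_t, double> > out(tab.begin(), tab.end());
    std::sort(out.begin(), out.end());
    IntegerVector counts(out.size());
    CharacterVector names(out.size());
    for (size_t i = 0; i < out.size(); ++i) {
      counts[i] = (int)out[i].second;
      names[i] = decode_kmer(out[i].first, k);
    }
    counts.attr("names") = names;
    return counts;
  }
  // string fallback for k > 32
  std::map<std::string, double> tab;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* str = CHAR(STRING_ELT(seqs, s));
    int n = LENGTH(STRING_ELT(seqs, s));
    if (n < k) continue;
    std::vector<int> ok(n);
    for (int i = 0; i < n; ++i) ok[i] = base2bits(str[i]) >= 0 ? 1 : 0;
    int valid_run = 0;
    for (int i = 0; i < n; ++i) {
      valid_run = ok[i] ? valid_run + 1 : 0;
      if (valid_run >= k) {
        std::string fwd(str + i - k + 1, str + i + 1);
        for (auto& c : fwd) c = BITS2BASE[base2bits(c)];
        if (canonical) {
          std::string rc = revcomp(fwd);
          tab[std::min(fwd, rc)] += 1.0;
        } else {
          tab[fwd] += 1.0;
        }
      }
    }
  }
  IntegerVector counts(tab.size());
  CharacterVector names(tab.size());
  size_t i = 0;
  for (auto& kv : tab) { names[i] = kv.first; counts[i] = (int)kv.second; ++i; }
  counts.attr("names") = names;
  return counts;
}

// Canonical form (lexicographic min of k-mer and reverse complement);
// NA for k-mers containing non-ACGT characters.
// [[Rcpp::export]]
CharacterVector cpp_canonicalize(CharacterVector kmers) {
  CharacterVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    if (kmers[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(kmers[i]);
    bool bad = false;
    for (auto& c : s) {
      int b = base2bits(c);
      if (b < 0) { bad = true; break; }
      c = BITS2BASE[b];
    }
    if (bad) { out[i] = NA_STRING; continue; }
    std::string rc = revcomp(s);
    out[i] = (rc < s) ? rc : s;
  }
  return out;
}

// Monte-Carlo chance-match trials: per trial, draw a random genome of
// length L and a random k-mer from the same base composition, then test
// whether the k-mer occurs in the genome text (forward) and whether its
// reverse complement does (reverse).  Uses the R RNG, so results are
// reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector cpp_monte_carlo_match(NumericVector probs, int k, int L,
                                    int trials) {
  if (k > L) stop("k must not exceed L");
  double cA = probs[0], cC = cA + probs[1], cG = cC + probs[2];
  int fwd_hits = 0, rev_hits = 0;
  std::string genome(L, 'A'), kmer(k, 'A');
  for (int t = 0; t < trials; ++t) {
    for (int i = 0; i < L; ++i) {
      double u = unif_rand();
      genome[i] = u < cA ? 'A' : (u < cC ? 'C' : (u < cG ? 'G' : 'T'));
    }
    for (int i = 0; i < k; ++i) {
      double u = unif_rand();
      kmer[i] = u < cA ? 'A' : (u < cC ? 'C' : (u < cG ? 'G' : 'T'));
    }
    if (genome.find(kmer) != std::string::npos) ++fwd_hits;
    std::string rc = revcomp(kmer);
    if (genome.find(rc) != std::string::npos) ++rev_hits;
  }
  return IntegerVector::create(Named("forward") = fwd_hits,
                               Named("reverse") = rev_hits);
}

static inline uint64_t mix64(uint64_t h) {
  h ^= h >> 30; h *= 0xbf58476d1ce4e5b9ULL;
  h ^= h >> 27; h *= 0x94d049bb133111ebULL;
  h ^= h >> 31;
  return h;
}

static inline uint64_t hash_bytes(const char* s, int n, uint64_t seed) {
  uint64_t h = seed ^ 0xcbf29ce484222325ULL;  // seeded FNV-1a + finalizer
  for (int i = 0; i < n; ++i) {
    h ^= (uint64_t)(uint8_t)s[i];
    h *= 0x100000001b3ULL;
  }
  return mix64(h);
}

static inline void cbf_positions(const char* s, int n, int m, int h,
                                 uint64_t seed, std::vector<int>& pos) {
  uint64_t ha = hash_bytes(s, n, seed * 0x9E3779B97F4A7C15ULL + 1ULL);
  uint64_t hb = hash_bytes(s, n, seed * 0xC2B2AE3D27D4EB4FULL + 2ULL) | 1ULL;
  for (int i = 0; i < h; ++i)
    pos[i] = (int)((ha + (uint64_t)i * hb) % (uint64_t)m);
}

// Double-hashed positions of each k-mer in an m-element filter.
// [[Rcpp::export]]
IntegerMatrix cpp_cbf_positions(CharacterVector kmers, int m, int h,
                                int seed) {
  IntegerMatrix out(kmers.size(), h);
  std::vector<int> pos(h);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    cbf_positions(s, LENGTH(STRING_ELT(kmers, i)), m, h,
                  (uint64_t)(uint32_t)seed, pos);
    for (int j = 0; j < h; ++j) out(i, j) = pos[j];
  }
  return out;
}

// Accumulate counts into a counting bloom filter with saturating
// 16-bit counters (ceiling 65535).
// [[Rcpp::export]]
IntegerVector cpp_cbf_compress(CharacterVector kmers, IntegerVector counts,
                               int m, int h, int seed) {
  std::vector<uint32_t> arr(m, 0u);
  std::vector<int> pos(h);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    cbf_positions(s, LENGTH(STRING_ELT(kmers, i)), m, h,
                  (uint64_t)(uint32_t)seed, pos);
    uint32_t c = (uint32_t)counts[i];
    for (int j = 0; j < h; ++j) {
      uint32_t v = arr[pos[j]] + c;
      arr[pos[j]] = v > 65535u ? 65535u : v;
    }
  }
  IntegerVector out(m);
  for (int i = 0; i < m; ++i) out[i] = (int)arr[i];
  return out;
}

// Pairwise Hamming distances between equal-length sequences.
// [[Rcpp::export]]
NumericMatrix cpp_pairwise_hamming(CharacterVector seqs) {
  int n = seqs.size();
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    const char* a = CHAR(STRING_ELT(seqs, i));
    int la = LENGTH(STRING_ELT(seqs, i));
    for (int j = i + 1; j < n; ++j) {
      const char* b = CHAR(STRING_ELT(seqs, j));
      if (LENGTH(STRING_ELT(seqs, j)) != la)
        stop("sequences must have equal length");
      double diff = 0;
      for (int p = 0; p < la; ++p) if (a[p] != b[p]) diff += 1;
      d(i, j) = diff;
      d(j, i) = diff;
    }
  }
  return d;
}
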