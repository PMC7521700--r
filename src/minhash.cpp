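#include <Rcpp.h>
#include <cstdint>
#include <set>
#include <string>
using namespace Rcpp;

// 64-bit avalanche mix (MurmurHash3 finalizer)
static inline uint64_t fmix64(uint64_t h) {
  h ^= h >> 33;
  h *= 0xff51afd7ed558ccdULL;
  h ^= h >> 33;
  h *= 0xc4ceb9fe1a85ec53ULL;
  h ^= h >> 33;
  return h;
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Bottom-s MinHash hash values over canonical k-mers.
//
// Canonical k-mer = min of the 2-bit packed forward and
// reverse-complement codes; the packed code is mixed with the seed and
// avalanched, and the hash is truncated to 53 bits so R doubles hold it
// exactly. k-mers containing non-ACGT letters are skipped. Returns the
// sketch_size smallest distinct hash values, sorted increasing.
// [[Rcpp::export]]
NumericVector minhash_hashes_cpp(CharacterVector seqs, int k,
                                 double sketch_size, int seed) {
  if (k < 1 || k > 31) stop("k must be in 1..31 (2-bit packing limit)");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const uint64_t seed_mix =
      fmix64(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 1ULL);
  std::set<uint64_t> hashes;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    uint64_t fw = 0, rc = 0;
    int filled = 0;
    for (size_t i = 0; i < seq.size(); ++i) {
      int c = base_code(seq[i]);
      if (c < 0) { filled = 0; fw = 0; rc = 0; continue; }
      fw = ((fw << 2) | static_cast<uint64_t>(c)) & mask;
      rc = (rc >> 2) |
           (static_cast<uint64_t>(3 - c) << (2 * (k - 1)));
      if (++filled >= k) {
        uint64_t canon = fw < rc ? fw : rc;
        hashes.insert(fmix64(canon ^ seed_mix) >> 11);  // 53-bit
      }
    }
  }
  R_xlen_t keep = hashes.size();
  if (sketch_size < static_cast<double>(keep))
    keep = static_cast<R_xlen_t>(sketch_size);
  NumericVector out(keep);
  R_xlen_t i = 0;
  for (std::set<uint64_t>::const_iterator it = hashes.begin();
       it != hashes.end() && i < keep; ++it, ++i) {
    out[i] = static_cast<double>(*it);
  }
  return out;
}
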