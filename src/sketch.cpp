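#include <Rcpp.h>
#include <cstdint>
#include <set>
#include <vector>

using namespace Rcpp;

// 64-bit mixer (splitmix64 finalizer); applied to the 2-bit packed canonical
// k-mer plus a seed so sketches are deterministic per (k, seed).
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
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

// Bottom-s sketch of canonical k-mers over a set of sequences.
// Returns sorted hash values scaled to [0, 1) doubles (53-bit precision is
// ample for collision-free MinHash at these sketch sizes), plus the number
// of k-mer windows skipped because they overlap a non-ACGT character.
// [[Rcpp::export(name = ".sketch_cpp")]]
List sketch_cpp(CharacterVector seqs, int k, int s, double seed) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  uint64_t seed64 = (uint64_t)seed;
  std::set<uint64_t> bottom; // ordered; largest element is max
  long long skipped = 0;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  for (int si = 0; si < seqs.size(); ++si) {
    const char* str = CHAR(STRING_ELT(seqs, si));
    int n = LENGTH(STRING_ELT(seqs, si));
    if (n < k) continue;
    uint64_t fwd = 0, rev = 0;
    int valid = 0; // number of consecutive valid bases ending here
    for (int i = 0; i < n; ++i) {
      int c = base_code(str[i]);
      if (c < 0) {
        // windows overlapping this position are skipped
        int lost = std::min(k, n - i) - std::max(0, k - 1 - i) ;
        // count windows [i-k+1, i] .. clipped to sequence, that were not
        // already invalidated; simpler exact count handled below via valid
        valid = 0;
        fwd = rev = 0;
        (void)lost;
        continue;
      }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | (((uint64_t)(3 - c)) << (2 * (k - 1)));
      if (valid < k) ++valid;
      if (valid >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        uint64_t h = mix64(canon ^ seed64);
        if ((int)bottom.size() < s) {
          bottom.insert(h);
        } else if (h < *bottom.rbegin()) {
          bottom.insert(h);
          if ((int)bottom.size() > s) bottom.erase(std::prev(bottom.end()));
        }
      }
    }
  }
  // exact skipped-window count: total windows minus hashed windows requires a
  // second pass; compute directly instead
  long long total_windows = 0, hashed = 0;
  for (int si = 0; si < seqs.size(); ++si) {
    const char* str = CHAR(STRING_ELT(seqs, si));
    int n = LENGTH(STRING_ELT(seqs, si));
    if (n >= k) total_windows += (long long)(n - k + 1);
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      if (base_code(str[i]) < 0) valid = 0; else if (valid < k) ++valid;
      if (valid >= k) ++hashed;
    }
  }
  skipped = total_windows - hashed;
  NumericVector out(bottom.size());
  int i = 0;
  for (std::set<uint64_t>::iterator it = bottom.begin(); it != bottom.end(); ++it) {
    out[i++] = (double)(*it >> 11) / 9007199254740992.0; // 2^53
  }
  return List::create(_["hashes"] = out, _["n_skipped"] = (double)skipped);
}
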