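#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit encode; returns 4 for anything not ACGT (case-insensitive)
static inline uint64_t code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

// Canonical k-mer counting over a set of reads.  A k-mer and its reverse
// complement are collapsed onto the lexicographically smaller encoding, as
// done by canonical-mode k-mer counters.  Windows containing non-ACGT
// symbols are skipped and tallied separately.
// [[Rcpp::export]]
List count_kmers_cpp(CharacterVector reads, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::unordered_map<uint64_t, uint32_t> tab;
  tab.reserve(1 << 20);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift_rc = 2 * (k - 1);
  double skipped = 0.0, emitted = 0.0;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int n = (int) LENGTH(STRING_ELT(reads, r));
    if (n < k) continue;
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      uint64_t c = code(s[i]);
      if (c > 3) {
        valid = 0; fwd = 0; rev = 0;
        // every window covering this base is skipped
        continue;
      }
      fwd = ((fwd << 2) | c) & mask;
      rev = (rev >> 2) | ((3 - c) << shift_rc);
      if (++valid >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++tab[canon];
        emitted += 1.0;
      }
    }
    // count skipped windows: total windows minus emitted for this read is
    // accumulated globally below
  }
  // total possible windows
  double total_windows = 0.0;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    int n = (int) LENGTH(STRING_ELT(reads, r));
    if (n >= k) total_windows += (double)(n - k + 1);
  }
  skipped = total_windows - emitted;
  // histogram: multiplicity -> number of distinct canonical k-mers
  std::unordered_map<uint32_t, double> hist;
  for (auto &kv : tab) hist[kv.second] += 1.0;
  std::vector<uint32_t> mult;
  mult.reserve(hist.size());
  for (auto &kv : hist) mult.push_back(kv.first);
  std::sort(mult.begin(), mult.end());
  IntegerVector m(mult.size());
  NumericVector cnt(mult.size());
  for (size_t i = 0; i < mult.size(); ++i) {
    m[i] = (int) mult[i];
    cnt[i] = hist[mult[i]];
  }
  return List::create(_["multiplicity"] = m, _["count"] = cnt,
                      _["instances"] = emitted, _["skipped"] = skipped);
}
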