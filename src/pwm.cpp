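#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int idx(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Slide a log-odds position weight matrix (4 x W, rows A,C,G,T) along each
// sequence and report the best-scoring window.  Forward strand only; the
// caller scans the reverse complement separately.  Sequences shorter than
// the profile get score -Inf and offset NA.
// [[Rcpp::export]]
DataFrame pwm_scan_cpp(NumericMatrix pwm, CharacterVector seqs) {
  int W = pwm.ncol();
  int n = seqs.size();
  NumericVector best(n, R_NegInf);
  IntegerVector at(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int L = (int) LENGTH(STRING_ELT(seqs, i));
    if (L < W) continue;
    for (int o = 0; o <= L - W; ++o) {
      double sc = 0.0;
      for (int w = 0; w < W; ++w) {
        int b = idx(s[o + w]);
        if (b < 0) { sc += -2.0; continue; } // ambiguous base penalty
        sc += pwm(b, w);
      }
      if (sc > best[i]) { best[i] = sc; at[i] = o; }
    }
  }
  return DataFrame::create(_["score"] = best, _["offset"] = at);
}
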