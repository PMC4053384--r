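#ifndef HEXALIGN_COMMON_H
#define HEXALIGN_COMMON_H

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

// 2-na base codes: A=0, C=1, G=2, T=3; anything else (N, IUPAC) -> -1
inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char code_base(int v) {
  static const char b[4] = {'A', 'C', 'G', 'T'};
  return b[v & 3];
}

inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

// iterate all valid (N-free) K-mer starts of s with their 2-na codes,
// restricted to starts that are multiples of `step`
template <class F>
inline void for_each_kmer(const std::string& s, int K, int step, F&& f) {
  const uint64_t mask = (K >= 32) ? ~0ull : ((1ull << (2 * K)) - 1);
  uint64_t code = 0;
  int run = 0;
  for (size_t j = 0; j < s.size(); ++j) {
    int c = base_code(s[j]);
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)c) & mask;
    if (++run >= K) {
      size_t i = j - (size_t)K + 1;
      if (step == 1 || (i % (size_t)step) == 0) f(i, code);
    }
  }
}

#endif
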