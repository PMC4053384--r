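#include "hex_common.h"
using namespace Rcpp;

// Pack an ACGT string into 2-bit codes, first base in the most significant
// bits of each byte so integer order of k-mer codes equals lexicographic
// order of k-mers.
// [[Rcpp::export]]
List cpp_encode_2na(std::string seq) {
  R_xlen_t n = (R_xlen_t)seq.size();
  if (n == 0) stop("cannot 2-bit encode an empty sequence");
  RawVector packed((n + 3) / 4);
  for (R_xlen_t i = 0; i < n; ++i) {
    int c = base_code(seq[(size_t)i]);
    if (c < 0)
      stop("non-ACGT base '" + std::string(1, seq[(size_t)i]) +
           "' at position " + std::to_string(i + 1) +
           " cannot be 2-bit encoded");
    packed[i >> 2] = (Rbyte)(packed[i >> 2] | (c << (6 - 2 * (i & 3))));
  }
  return List::create(_["packed"] = packed, _["length"] = (double)n);
}

// [[Rcpp::export]]
std::string cpp_decode_2na(RawVector packed, double length) {
  R_xlen_t n = (R_xlen_t)length;
  if (n < 0 || (n + 3) / 4 > packed.size())
    stop("stated length does not fit the packed payload");
  std::string out((size_t)n, 'A');
  for (R_xlen_t i = 0; i < n; ++i) {
    int v = (packed[i >> 2] >> (6 - 2 * (i & 3))) & 3;
    out[(size_t)i] = code_base(v);
  }
  return out;
}

// 2-na integer code of the K-mer at 0-based `offset`; NA when the window
// contains an ambiguity base (unindexable k-mer).
// [[Rcpp::export]]
double cpp_kmer_code(std::string seq, int offset, int K) {
  if (K < 1 || K > 26)
    stop("K must be in 1..26 (codes above K=26 are not exactly representable)");
  if (offset < 0 || (size_t)offset + (size_t)K > seq.size())
    stop("k-mer window [offset, offset+K) outside the sequence");
  uint64_t v = 0;
  for (int i = 0; i < K; ++i) {
    int c = base_code(seq[(size_t)offset + (size_t)i]);
    if (c < 0) return NA_REAL;
    v = (v << 2) | (uint64_t)c;
  }
  return (double)v;
}

// [[Rcpp::export]]
std::string cpp_code_to_kmer(double code, int K) {
  if (K < 1 || K > 26) stop("K must be in 1..26");
  if (ISNA(code) || code < 0) stop("invalid k-mer code");
  uint64_t v = (uint64_t)code;
  std::string out((size_t)K, 'A');
  for (int i = K - 1; i >= 0; --i) {
    out[(size_t)i] = code_base((int)(v & 3));
    v >>= 2;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j)
      r[j] = comp_base(s[s.size() - 1 - j]);
    out[i] = r;
  }
  return out;
}

// longest common prefix length (in bases) of paired strings
// [[Rcpp::export]]
IntegerVector cpp_lcp(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size()) stop("cpp_lcp: length mismatch");
  IntegerVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    const char* x = CHAR(STRING_ELT(a, i));
    const char* y = CHAR(STRING_ELT(b, i));
    int m = 0;
    while (x[m] != '\0' && y[m] != '\0' && x[m] == y[m]) ++m;
    out[i] = m;
  }
  return out;
}
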