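#include "hex_common.h"
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Direct-addressed K-mer bucket table over the reference set.
// The 2-na code of a K-mer is its bucket address (no hashing, no
// collisions). A one-bit-per-code presence table (single-hash, exact
// "bloom") is consulted before any bucket fetch; buckets whose occupancy
// exceeds the over-expression threshold are masked (flagged, not deleted).
// Bucket entries are laid out with a counting sort into two flat arrays,
// so per-bucket entries are ordered by (reference ordinal, position).

struct KmerIndex {
  int K = 0, T = 0, step = 1;
  long long nbuckets = 0;
  std::vector<uint64_t> bloom;     // 1 bit per code: bucket non-empty pre-mask
  std::vector<uint64_t> maskbits;  // 1 bit per code: bucket over-expressed
  std::vector<uint32_t> bucket_end; // end offset of bucket c in eref/epos
  std::vector<int32_t> eref, epos;  // entries
  std::vector<std::string> ref_seq, ref_id;
  long long n_masked = 0, n_nonempty = 0;
};

static inline bool bit_get(const std::vector<uint64_t>& v, uint64_t i) {
  return (v[i >> 6] >> (i & 63)) & 1ull;
}
static inline void bit_set(std::vector<uint64_t>& v, uint64_t i) {
  v[i >> 6] |= (1ull << (i & 63));
}

// per-reference indexability mask from the optional low-complexity filter:
// tile the reference into `window`-base tiles and exclude seed starts in
// tiles whose 2-mer Shannon entropy (bits) falls below `min_entropy`
static std::vector<char> entropy_allowed(const std::string& s, int window,
                                         double min_entropy) {
  std::vector<char> ok(s.size(), 1);
  if (min_entropy <= 0) return ok;
  for (size_t t0 = 0; t0 < s.size(); t0 += (size_t)window) {
    size_t t1 = std::min(s.size(), t0 + (size_t)window);
    if (t1 - t0 < 2) continue;
    int cnt[16] = {0};
    int tot = 0;
    for (size_t j = t0; j + 1 < t1; ++j) {
      int a = base_code(s[j]), b = base_code(s[j + 1]);
      if (a < 0 || b < 0) continue;
      cnt[a * 4 + b]++;
      tot++;
    }
    if (tot == 0) continue;
    double H = 0;
    for (int i = 0; i < 16; ++i)
      if (cnt[i] > 0) {
        double p = (double)cnt[i] / tot;
        H -= p * std::log2(p);
      }
    if (H < min_entropy)
      for (size_t j = t0; j < t1; ++j) ok[j] = 0;
  }
  return ok;
}

// [[Rcpp::export]]
SEXP cpp_ki_build(CharacterVector ref_seqs, CharacterVector ref_ids, int K,
                  int T, int step, double min_entropy, int entropy_window) {
  if (K < 1 || K > 14)
    stop("index seed length K must be in 1..14; for longer seeds use "
         "double-lookup mode (seed_len > K at lookup time)");
  if (T < 1) stop("over-expression threshold T must be >= 1");
  if (step < 1) stop("position step must be >= 1");
  XPtr<KmerIndex> xp(new KmerIndex(), true);
  KmerIndex& ix = *xp;
  ix.K = K; ix.T = T; ix.step = step;
  ix.nbuckets = 1ll << (2 * K);
  ix.ref_seq.reserve((size_t)ref_seqs.size());
  ix.ref_id.reserve((size_t)ref_seqs.size());
  for (R_xlen_t r = 0; r < ref_seqs.size(); ++r) {
    std::string s = as<std::string>(ref_seqs[r]);
    for (auto& c : s) c = (char)toupper((unsigned char)c);
    if (s.empty()) stop("reference sequences must be non-empty");
    ix.ref_seq.push_back(std::move(s));
    ix.ref_id.push_back(as<std::string>(ref_ids[r]));
  }

  std::vector<std::vector<char>> allow;
  if (min_entropy > 0) {
    allow.reserve(ix.ref_seq.size());
    for (auto& s : ix.ref_seq)
      allow.push_back(entropy_allowed(s, entropy_window, min_entropy));
  }

  ix.bucket_end.assign((size_t)ix.nbuckets, 0u);
  // pass 1: occupancy counts
  for (size_t r = 0; r < ix.ref_seq.size(); ++r) {
    const char* ok = allow.empty() ? nullptr : allow[r].data();
    for_each_kmer(ix.ref_seq[r], K, step, [&](size_t i, uint64_t code) {
      if (ok && !ok[i]) return;
      ix.bucket_end[(size_t)code]++;
    });
  }
  // presence bits, masking, exclusive scan (in place -> start offsets)
  ix.bloom.assign((size_t)((ix.nbuckets + 63) >> 6), 0ull);
  ix.maskbits.assign((size_t)((ix.nbuckets + 63) >> 6), 0ull);
  uint64_t run = 0;
  for (long long c = 0; c < ix.nbuckets; ++c) {
    uint32_t n = ix.bucket_end[(size_t)c];
    if (n > 0) { bit_set(ix.bloom, (uint64_t)c); ix.n_nonempty++; }
    if ((long long)n > (long long)T) { bit_set(ix.maskbits, (uint64_t)c); ix.n_masked++; }
    ix.bucket_end[(size_t)c] = (uint32_t)run; // start offset for pass 2
    run += n;
  }
  ix.eref.resize((size_t)run);
  ix.epos.resize((size_t)run);
  // pass 2: place entries; bucket_end becomes the end offset per bucket
  for (size_t r = 0; r < ix.ref_seq.size(); ++r) {
    const char* ok = allow.empty() ? nullptr : allow[r].data();
    for_each_kmer(ix.ref_seq[r], K, step, [&](size_t i, uint64_t code) {
      if (ok && !ok[i]) return;
      uint32_t at = ix.bucket_end[(size_t)code]++;
      ix.eref[at] = (int32_t)r;
      ix.epos[at] = (int32_t)i;
    });
  }
  return xp;
}

static inline void bucket_range(const KmerIndex& ix, uint64_t code,
                                uint32_t& lo, uint32_t& hi) {
  lo = (code == 0) ? 0u : ix.bucket_end[(size_t)code - 1];
  hi = ix.bucket_end[(size_t)code];
}

// rolling 2-na codes of every K-window of `s`; -1 marks unindexable windows
static std::vector<int64_t> window_codes(const std::string& s, int K) {
  std::vector<int64_t> codes;
  if ((int)s.size() < K) return codes;
  codes.assign(s.size() - (size_t)K + 1, -1);
  for_each_kmer(s, K, 1, [&](size_t i, uint64_t code) {
    codes[i] = (int64_t)code;
  });
  return codes;
}

// Candidate discovery for one read. Consults the presence bit before any
// bucket fetch; masked buckets contribute no hits; hits are de-duplicated
// on (reference, diagonal) keeping the leftmost read offset, with the seed
// count per diagonal retained for best-first ranking. seed_len > K turns on
// double lookup: two exact sub-K-mer matches at read offsets roff and
// roff + (seed_len - K) on the same diagonal (continuous coverage of the
// full seed_len window).
// [[Rcpp::export]]
List cpp_ki_lookup(SEXP index, std::string read, int seed_len) {
  XPtr<KmerIndex> xp(index);
  const KmerIndex& ix = *xp;
  if (ix.nbuckets == 0) stop("this k-mer index has been released");
  for (auto& c : read) c = (char)toupper((unsigned char)c);
  if (seed_len <= 0) seed_len = ix.K;
  if (seed_len < ix.K || seed_len > 2 * ix.K)
    stop("seed_len must be in [K, 2K] for this index");
  const bool dbl = seed_len > ix.K;
  const int delta = seed_len - ix.K;

  long long n_offsets = 0, bloom_hits = 0, bucket_fetches = 0, raw_hits = 0,
            masked_skips = 0;
  std::vector<int> href, hpos, hroff, hnseed;
  std::unordered_map<uint64_t, int> seen; // (ref, diagonal) -> hit slot

  std::vector<int64_t> codes = window_codes(read, ix.K);
  int L = (int)read.size();
  int last = L - seed_len;
  for (int roff = 0; roff <= last; ++roff) {
    int64_t c1 = codes.empty() ? -1 : codes[(size_t)roff];
    if (c1 < 0) continue;
    int64_t c2 = 0;
    if (dbl) {
      c2 = codes[(size_t)(roff + delta)];
      if (c2 < 0) continue;
    }
    n_offsets++;
    if (!bit_get(ix.bloom, (uint64_t)c1)) continue;
    bloom_hits++;
    if (bit_get(ix.maskbits, (uint64_t)c1)) { masked_skips++; continue; }
    if (dbl) {
      if (!bit_get(ix.bloom, (uint64_t)c2)) continue;
      if (bit_get(ix.maskbits, (uint64_t)c2)) { masked_skips++; continue; }
    }
    uint32_t lo, hi;
    bucket_range(ix, (uint64_t)c1, lo, hi);
    bucket_fetches++;
    uint32_t lo2 = 0, hi2 = 0;
    if (dbl) { bucket_range(ix, (uint64_t)c2, lo2, hi2); bucket_fetches++; }
    for (uint32_t e = lo; e < hi; ++e) {
      int r = ix.eref[e], p = ix.epos[e];
      if (dbl) {
        // entries are (ref, pos)-sorted: binary search the partner sub-seed
        int want = p + delta;
        uint32_t a = lo2, b = hi2;
        bool found = false;
        while (a < b) {
          uint32_t mid = a + (b - a) / 2;
          int mr = ix.eref[mid], mp = ix.epos[mid];
          if (mr < r || (mr == r && mp < want)) a = mid + 1;
          else if (mr == r && mp == want) { found = true; break; }
          else b = mid;
        }
        if (!found) continue;
      }
      raw_hits++;
      int64_t diag = (int64_t)p - (int64_t)roff;
      uint64_t key = ((uint64_t)(uint32_t)r << 33) ^
                     (uint64_t)(diag + (int64_t)L + 1);
      auto it = seen.find(key);
      if (it == seen.end()) {
        seen.emplace(key, (int)href.size());
        href.push_back(r);
        hpos.push_back(p);
        hroff.push_back(roff);
        hnseed.push_back(1);
      } else {
        hnseed[(size_t)it->second]++; // leftmost roff kept: roff increases
      }
    }
  }
  return List::create(
      _["ref"] = wrap(href), _["pos"] = wrap(hpos), _["read_offset"] = wrap(hroff),
      _["n_seeds"] = wrap(hnseed),
      _["counters"] = List::create(
          _["n_offsets"] = (double)n_offsets, _["bloom_hits"] = (double)bloom_hits,
          _["bucket_fetches"] = (double)bucket_fetches,
          _["raw_hits"] = (double)raw_hits,
          _["masked_skips"] = (double)masked_skips));
}

// [[Rcpp::export]]
List cpp_ki_info(SEXP index) {
  XPtr<KmerIndex> xp(index);
  return List::create(
      _["K"] = xp->K, _["threshold"] = xp->T, _["step"] = xp->step,
      _["n_buckets"] = (double)xp->nbuckets,
      _["n_entries"] = (double)xp->eref.size(),
      _["n_nonempty"] = (double)xp->n_nonempty,
      _["n_masked"] = (double)xp->n_masked,
      _["n_refs"] = (double)xp->ref_seq.size());
}

// [[Rcpp::export]]
List cpp_ki_bucket(SEXP index, std::string kmer) {
  XPtr<KmerIndex> xp(index);
  if (xp->nbuckets == 0) stop("this k-mer index has been released");
  if ((int)kmer.size() != xp->K) stop("k-mer length must equal index K");
  uint64_t code = 0;
  for (char c : kmer) {
    int v = base_code(c);
    if (v < 0) stop("k-mer contains an ambiguity base");
    code = (code << 2) | (uint64_t)v;
  }
  uint32_t lo, hi;
  bucket_range(*xp, code, lo, hi);
  IntegerVector rref(hi - lo), rpos(hi - lo);
  for (uint32_t e = lo; e < hi; ++e) {
    rref[e - lo] = xp->eref[e];
    rpos[e - lo] = xp->epos[e];
  }
  return List::create(_["ref"] = rref, _["pos"] = rpos,
                      _["bloom"] = bit_get(xp->bloom, code),
                      _["masked"] = bit_get(xp->maskbits, code));
}

// [[Rcpp::export]]
CharacterVector cpp_ki_ref_ids(SEXP index) {
  XPtr<KmerIndex> xp(index);
  return wrap(xp->ref_id);
}

// release the bulky arrays eagerly (without waiting for gc finalizers)
// [[Rcpp::export]]
void cpp_ki_release(SEXP index) {
  XPtr<KmerIndex> xp(index);
  std::vector<uint32_t>().swap(xp->bucket_end);
  std::vector<uint64_t>().swap(xp->bloom);
  std::vector<uint64_t>().swap(xp->maskbits);
  std::vector<int32_t>().swap(xp->eref);
  std::vector<int32_t>().swap(xp->epos);
  xp->nbuckets = 0;
}
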