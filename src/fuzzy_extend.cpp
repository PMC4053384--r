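#include "hex_common.h"
#include <climits>
#include <cmath>
using namespace Rcpp;

// Bidirectional fuzzy extension of an exact seed match.
// Each direction runs a small banded integer DP (match +1, mismatch -1,
// gap open -2, gap extend -1; a gap of n bases costs open + n*extend) in a
// floating window of excursion |d| <= win around the seed diagonal. The
// front advances one read base per row; extension stops when the
// mismatch+indel density over a trailing window of rows exceeds the
// allowance, or when either sequence ends. The endpoint is the last
// accepted front row, so trailing substitutions near a read end stay
// inside the bracket and the downstream optimal aligner makes the call.

static const int NEG = INT_MIN / 4;
static const int EXT_MATCH = 1, EXT_MISM = -1, EXT_OPEN = -2, EXT_EXT = -1;

struct ExtDir {
  int t = 0;      // read bases consumed
  int d = 0;      // excursion: ref consumed - read consumed
  int score = 0;
  int mm = 0, gi = 0, gd = 0; // mismatches, read-gap bases (I), ref-gap bases (D)
};

// full front (brackets the frame) + score-argmax front (the extension's
// own analogue of Smith-Waterman edge trimming; drives the pass decision)
struct ExtPair {
  ExtDir front;
  ExtDir best;
};

// dir = +1 extends right of the seed, -1 extends left.
// ra/qa are the exclusive anchor offsets in read/ref; maxT/maxQ the number
// of read/ref bases available in this direction.
static ExtPair extend_dir(const std::string& read, const std::string& ref,
                         int ra, int qa, int maxT, int maxQ, int dir, int win,
                         double allow_frac, int dens_win) {
  const int W = 2 * win + 1;
  std::vector<int> prevH(W, NEG), prevF(W, NEG), curH(W), curF(W), curE(W);
  std::vector<int> pMM(W, 0), pGI(W, 0), pGD(W, 0);
  std::vector<int> cMM(W), cGI(W), cGD(W), eMM(W), eGI(W), eGD(W);
  std::vector<int> pFM(W, 0), pFGI(W, 0), pFGD(W, 0);
  std::vector<int> cFM(W), cFGI(W), cFGD(W);

  auto rdchar = [&](int t) { return dir > 0 ? read[(size_t)(ra + t - 1)]
                                            : read[(size_t)(ra - t)]; };
  auto rfchar = [&](int q) { return dir > 0 ? ref[(size_t)(qa + q - 1)]
                                            : ref[(size_t)(qa - q)]; };

  // row 0: only leading ref gaps (d >= 0) are reachable
  for (int s = 0; s < W; ++s) {
    int d = s - win;
    if (d >= 0 && d <= maxQ) {
      prevH[s] = (d == 0) ? 0 : EXT_OPEN + d * EXT_EXT;
      pGD[s] = d;
    }
  }

  std::vector<ExtDir> rowbest((size_t)maxT + 1);
  rowbest[0] = ExtDir(); // t=0, d=0, all zero
  int tE = 0;

  for (int t = 1; t <= maxT; ++t) {
    bool any = false;
    for (int s = 0; s < W; ++s) {
      int d = s - win, q = t + d;
      curH[s] = curF[s] = curE[s] = NEG;
      cMM[s] = cGI[s] = cGD[s] = 0;
      if (q < 0 || q > maxQ) continue;
      int best = NEG, bmm = 0, bgi = 0, bgd = 0;
      // diagonal (match/mismatch)
      if (q >= 1 && prevH[s] > NEG) {
        char x = rdchar(t), y = rfchar(q);
        bool isM = (x == y) && base_code(x) >= 0;
        int sc = prevH[s] + (isM ? EXT_MATCH : EXT_MISM);
        best = sc;
        bmm = pMM[s] + (isM ? 0 : 1);
        bgi = pGI[s];
        bgd = pGD[s];
      }
      // read gap (consumes read only): from previous row, d+1
      cFM[s] = cFGI[s] = cFGD[s] = 0;
      if (s + 1 < W) {
        int fo = (prevH[s + 1] > NEG) ? prevH[s + 1] + EXT_OPEN + EXT_EXT : NEG;
        int fe = (prevF[s + 1] > NEG) ? prevF[s + 1] + EXT_EXT : NEG;
        int f = fo >= fe ? fo : fe;
        curF[s] = f;
        if (f > NEG) {
          if (fo >= fe) { cFM[s] = pMM[s + 1]; cFGI[s] = pGI[s + 1] + 1; cFGD[s] = pGD[s + 1]; }
          else { cFM[s] = pFM[s + 1]; cFGI[s] = pFGI[s + 1] + 1; cFGD[s] = pFGD[s + 1]; }
          if (f > best) { best = f; bmm = cFM[s]; bgi = cFGI[s]; bgd = cFGD[s]; }
        }
      }
      if (best > NEG) {
        curH[s] = best;
        cMM[s] = bmm; cGI[s] = bgi; cGD[s] = bgd;
        any = true;
      }
    }
    // ref gap (consumes ref only): within-row sweep, d ascending
    for (int s = 1; s < W; ++s) {
      int d = s - win, q = t + d;
      if (q < 1 || q > maxQ) continue;
      int eo = (curH[s - 1] > NEG) ? curH[s - 1] + EXT_OPEN + EXT_EXT : NEG;
      int ee = (curE[s - 1] > NEG) ? curE[s - 1] + EXT_EXT : NEG;
      int e = eo >= ee ? eo : ee;
      curE[s] = e;
      if (e > NEG) {
        if (eo >= ee) { eMM[s] = cMM[s - 1]; eGI[s] = cGI[s - 1]; eGD[s] = cGD[s - 1] + 1; }
        else { eMM[s] = eMM[s - 1]; eGI[s] = eGI[s - 1]; eGD[s] = eGD[s - 1] + 1; }
        if (e > curH[s]) {
          curH[s] = e;
          cMM[s] = eMM[s]; cGI[s] = eGI[s]; cGD[s] = eGD[s];
          any = true;
        }
      }
    }
    if (!any) break;
    // row best: highest score, ties to smaller |d| then smaller d
    int bs = -1;
    for (int s = 0; s < W; ++s) {
      if (curH[s] <= NEG) continue;
      if (bs < 0) { bs = s; continue; }
      int d1 = std::abs(s - win), d0 = std::abs(bs - win);
      if (curH[s] > curH[bs] ||
          (curH[s] == curH[bs] && (d1 < d0 || (d1 == d0 && s - win < bs - win))))
        bs = s;
    }
    ExtDir rb;
    rb.t = t; rb.d = bs - win; rb.score = curH[bs];
    rb.mm = cMM[bs]; rb.gi = cGI[bs]; rb.gd = cGD[bs];
    rowbest[(size_t)t] = rb;
    // hopeless-density stops. These are deliberately loose (twice the
    // allowance, floored at 50% local error) so that the front only
    // terminates in regions no reportable alignment could cross; the
    // pass decision below, not the stop rule, does the actual filtering.
    int err_t = rb.mm + rb.gi + rb.gd;
    if ((double)err_t > 0.5 * t + 4.0) break;
    if (t >= dens_win) {
      const ExtDir& old = rowbest[(size_t)(t - dens_win)];
      int err_o = old.mm + old.gi + old.gd;
      double lim = std::max(2.0 * allow_frac, 0.5) * dens_win;
      if ((double)(err_t - err_o) > lim) break;
    }
    tE = t;
    std::swap(prevH, curH); std::swap(prevF, curF);
    std::swap(pMM, cMM); std::swap(pGI, cGI); std::swap(pGD, cGD);
    std::swap(pFM, cFM); std::swap(pFGI, cFGI); std::swap(pFGD, cFGD);
  }
  ExtPair out;
  out.front = rowbest[(size_t)tE];
  out.best = rowbest[0];
  for (int t = 1; t <= tE; ++t)
    if (rowbest[(size_t)t].score > out.best.score)
      out.best = rowbest[(size_t)t];
  return out;
}

static void extend_one(const std::string& read, const std::string& ref,
                       int roff, int rpos, int seed_len, int win,
                       double min_len_pct, double mism_pct, int dens_win,
                       double* out /* 11 values */) {
  int L = (int)read.size(), G = (int)ref.size();
  if (roff < 0 || rpos < 0 || roff + seed_len > L || rpos + seed_len > G)
    stop("seed coordinates outside read/reference (upstream index bug)");
  for (int i = 0; i < seed_len; ++i)
    if (read[(size_t)(roff + i)] != ref[(size_t)(rpos + i)])
      stop("seed does not verify as an exact match at its stated coordinates");

  ExtPair R = extend_dir(read, ref, roff + seed_len, rpos + seed_len,
                         L - roff - seed_len, G - rpos - seed_len, +1, win,
                         mism_pct / 100.0, dens_win);
  ExtPair Lt = extend_dir(read, ref, roff, rpos, roff, rpos, -1, win,
                          mism_pct / 100.0, dens_win);

  // frame tallies follow the full front (they describe the bracket);
  // the pass decision uses the score-argmax fronts, which trim edge
  // mismatches exactly as the downstream optimal aligner would
  int mm = R.front.mm + Lt.front.mm;
  int gi = R.front.gi + Lt.front.gi;
  int gd = R.front.gd + Lt.front.gd;
  int n_match = seed_len + (R.front.t - R.front.gi - R.front.mm) +
                (Lt.front.t - Lt.front.gi - Lt.front.mm);
  int score = seed_len * EXT_MATCH + R.best.score + Lt.best.score;
  int bext = seed_len + R.best.t + Lt.best.t;
  int berr = R.best.mm + R.best.gi + R.best.gd + Lt.best.mm + Lt.best.gi +
             Lt.best.gd;
  int min_len = (int)std::ceil(min_len_pct / 100.0 * L);
  double allow = mism_pct / 100.0;
  // +1 mismatch slack: the expensive stage, not the filter, makes final calls
  bool passed = (bext >= min_len) && ((double)berr <= allow * bext + 1.0);
  int required = (int)std::ceil(min_len * (1.0 - 2.0 * allow));
  double margin = passed ? -1.0 : std::max(0, required - score);

  out[0] = passed ? 1.0 : 0.0;
  out[1] = roff - Lt.front.t;                           // read start (0-based)
  out[2] = roff + seed_len + R.front.t;                 // read end (half-open)
  out[3] = rpos - (Lt.front.t + Lt.front.d);            // ref start
  out[4] = rpos + seed_len + R.front.t + R.front.d;     // ref end
  out[5] = score;
  out[6] = n_match;
  out[7] = mm;
  out[8] = gi;
  out[9] = gd;
  out[10] = margin;
}

// [[Rcpp::export]]
List cpp_fuzzy_extend(std::string read, std::string ref, int roff, int rpos,
                      int seed_len, double min_len_pct, double mism_pct,
                      int window, int dens_win) {
  for (auto& c : read) c = (char)toupper((unsigned char)c);
  for (auto& c : ref) c = (char)toupper((unsigned char)c);
  double v[11];
  extend_one(read, ref, roff, rpos, seed_len, window, min_len_pct, mism_pct,
             dens_win, v);
  return List::create(
      _["passed"] = v[0] > 0, _["read_start"] = (int)v[1],
      _["read_end"] = (int)v[2], _["ref_start"] = (int)v[3],
      _["ref_end"] = (int)v[4], _["score"] = (int)v[5],
      _["n_match"] = (int)v[6], _["n_mismatch"] = (int)v[7],
      _["n_ins"] = (int)v[8], _["n_del"] = (int)v[9], _["margin"] = v[10]);
}

// batch form used by the pipeline: one row per candidate seed hit
// [[Rcpp::export]]
NumericMatrix cpp_fuzzy_extend_batch(std::string read, CharacterVector ref_seqs,
                                     IntegerVector ref_ord, IntegerVector rpos,
                                     IntegerVector roff, int seed_len,
                                     double min_len_pct, double mism_pct,
                                     int window, int dens_win) {
  for (auto& c : read) c = (char)toupper((unsigned char)c);
  R_xlen_t n = ref_ord.size();
  NumericMatrix out(n, 11);
  colnames(out) = CharacterVector::create(
      "passed", "read_start", "read_end", "ref_start", "ref_end", "score",
      "n_match", "n_mismatch", "n_ins", "n_del", "margin");
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string ref = as<std::string>(ref_seqs[ref_ord[i]]);
    for (auto& c : ref) c = (char)toupper((unsigned char)c);
    double v[11];
    extend_one(read, ref, roff[i], rpos[i], seed_len, window, min_len_pct,
               mism_pct, dens_win, v);
    for (int j = 0; j < 11; ++j) out(i, j) = v[j];
  }
  return out;
}
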