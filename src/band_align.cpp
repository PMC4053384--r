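#include "hex_common.h"
#include <climits>
#include <cmath>
using namespace Rcpp;

// Smith-Waterman (optionally Needleman-Wunsch) restricted to a floating,
// variable-width diagonal band with affine gaps (a gap of n bases costs
// gap_open + n * gap_ext). The band of half-width w is re-centered each
// read row on the column of the previous row's maximum (the current
// highest-scoring path), moving at most +/- w per row so consecutive rows
// always overlap. Cells whose admissible score upper bound (current score
// plus all-match completion of the remaining read) cannot reach the
// reporting threshold are pruned ("holes"): excluded from computation and
// from the traceback. Storage is the linearized band, ~(2w+1) x L, never
// L x G.

static const int NEG = INT_MIN / 4;

struct Band {
  int n, m, width;
  std::vector<int> off, jlo, jhi;       // per-row band placement
  std::vector<int> H, E, F;             // linearized (n+1) x width
  std::vector<uint8_t> tb;
  Band(int n_, int m_, int w)
      : n(n_), m(m_), width(2 * w + 1), off(n_ + 1), jlo(n_ + 1), jhi(n_ + 1),
        H((size_t)(n_ + 1) * (2 * w + 1), NEG),
        E((size_t)(n_ + 1) * (2 * w + 1), NEG),
        F((size_t)(n_ + 1) * (2 * w + 1), NEG),
        tb((size_t)(n_ + 1) * (2 * w + 1), 0) {}
  inline size_t at(int t, int j) const {
    return (size_t)t * (size_t)width + (size_t)(j - off[t]);
  }
  inline bool inband(int t, int j) const {
    return j >= jlo[t] && j <= jhi[t];
  }
  inline int getH(int t, int j) const { return inband(t, j) ? H[at(t, j)] : NEG; }
  inline int getE(int t, int j) const { return inband(t, j) ? E[at(t, j)] : NEG; }
  inline int getF(int t, int j) const { return inband(t, j) ? F[at(t, j)] : NEG; }
};

// tb byte: bits 0-1 H source (0 start, 1 diag, 2 E, 3 F); bit 2 diag match;
// bit 3 E extends E; bit 4 F extends F
// [[Rcpp::export]]
List cpp_band_align(std::string read, std::string ref, int rs, int re, int qs,
                    int qe, int match, int mismatch, int gap_open, int gap_ext,
                    int w, bool prune, int min_len, double mism_pct,
                    bool global_mode, bool float_band, int center0) {
  for (auto& c : read) c = (char)toupper((unsigned char)c);
  for (auto& c : ref) c = (char)toupper((unsigned char)c);
  if (w < 1) stop("band half-width w must be >= 1");
  if (rs < 0 || qs < 0 || re > (int)read.size() || qe > (int)ref.size() ||
      rs >= re || qs >= qe)
    stop("bracket outside read/reference bounds");
  const int n = re - rs, m = qe - qs;
  const double a = mism_pct / 100.0;
  const int min_report_score =
      (int)std::ceil((double)min_len * (match * (1.0 - a) + mismatch * a));

  Band B(n, m, w);
  long long live = 0, holes = 0;
  // row 0, centered on the expected start diagonal of the bracket
  center0 = std::min(std::max(center0, 0), m);
  B.off[0] = center0 - w;
  B.jlo[0] = std::max(0, center0 - w);
  B.jhi[0] = std::min(m, center0 + w);
  for (int j = B.jlo[0]; j <= B.jhi[0]; ++j) {
    size_t ix = B.at(0, j);
    if (global_mode) {
      B.H[ix] = (j == 0) ? 0 : gap_open + j * gap_ext;
      B.E[ix] = (j == 0) ? NEG : gap_open + j * gap_ext;
      B.tb[ix] = (j == 0) ? 0 : (uint8_t)(2 | ((j > 1) ? 8 : 0));
    } else {
      B.H[ix] = 0;
      B.tb[ix] = 0;
    }
    live++;
  }
  int center_prev = center0;
  int best = global_mode ? NEG : 0, bt = 0, bj = 0;
  // best column of row 0: ties resolve to the column nearest the center,
  // so an all-zero local row does not drag the band off its diagonal
  int bestcol = center0;
  {
    int bv = NEG;
    for (int j = B.jlo[0]; j <= B.jhi[0]; ++j) {
      int h = B.H[B.at(0, j)];
      if (h > bv || (h == bv && std::abs(j - center0) <
                                    std::abs(bestcol - center0))) {
        bv = h;
        bestcol = j;
      }
    }
  }

  for (int t = 1; t <= n; ++t) {
    int center;
    if (float_band) {
      // drift toward the previous row's maximum by at most one column per
      // row (relative to the default diagonal advance): near-ties in
      // mismatch-rich rows make the raw row maximum bounce across the
      // band, and chasing it faster would throw the optimum out of band
      int desired = bestcol + 1;
      int lo = center_prev + 1 - 1, hi = center_prev + 1 + 1;
      center = std::min(std::max(desired, lo), hi);
    } else {
      center = center0 + t;
    }
    center = std::min(std::max(center, 0), m);
    B.off[t] = center - w;
    B.jlo[t] = std::max(0, center - w);
    B.jhi[t] = std::min(m, center + w);
    char x = read[(size_t)(rs + t - 1)];
    bool any = false;
    int rowbest = NEG, rowbestj = B.jlo[t];
    for (int j = B.jlo[t]; j <= B.jhi[t]; ++j) {
      size_t ix = B.at(t, j);
      // F: gap in reference (consumes read base t)
      int fH = B.getH(t - 1, j), fF = B.getF(t - 1, j);
      int fo = fH > NEG ? fH + gap_open + gap_ext : NEG;
      int fe = fF > NEG ? fF + gap_ext : NEG;
      int Fv = fo >= fe ? fo : fe;
      // E: gap in read (consumes ref base j), within-row
      int eH = (j > B.jlo[t]) ? B.H[B.at(t, j - 1)] : NEG;
      int eE = (j > B.jlo[t]) ? B.E[B.at(t, j - 1)] : NEG;
      int eo = eH > NEG ? eH + gap_open + gap_ext : NEG;
      int ee = eE > NEG ? eE + gap_ext : NEG;
      int Ev = eo >= ee ? eo : ee;
      // diagonal
      int Dv = NEG;
      bool ismatch = false;
      if (j >= 1) {
        int dH = B.getH(t - 1, j - 1);
        if (dH > NEG) {
          char y = ref[(size_t)(qs + j - 1)];
          ismatch = (x == y) && base_code(x) >= 0;
          Dv = dH + (ismatch ? match : mismatch);
        }
      }
      int Hv;
      uint8_t src;
      if (global_mode) {
        Hv = Dv;
        src = 1;
        if (Ev > Hv) { Hv = Ev; src = 2; }
        if (Fv > Hv) { Hv = Fv; src = 3; }
        if (Hv <= NEG) { src = 0; }
      } else {
        Hv = 0; src = 0;
        if (Dv > Hv) { Hv = Dv; src = 1; }
        if (Ev > Hv) { Hv = Ev; src = 2; }
        if (Fv > Hv) { Hv = Fv; src = 3; }
      }
      // admissible pruning: all-match completion of the remaining read
      if (prune && Hv > NEG) {
        long long ub = (long long)Hv + (long long)(n - t) * match;
        if (ub < min_report_score) {
          B.H[ix] = B.E[ix] = B.F[ix] = NEG;
          B.tb[ix] = 0;
          holes++;
          continue;
        }
      }
      if (Hv <= NEG && Ev <= NEG && Fv <= NEG) continue;
      B.H[ix] = Hv;
      B.E[ix] = Ev;
      B.F[ix] = Fv;
      B.tb[ix] = (uint8_t)(src | (ismatch ? 4 : 0) | ((ee > eo) ? 8 : 0) |
                           ((fe > fo) ? 16 : 0));
      live++;
      any = true;
      if (Hv > rowbest ||
          (Hv == rowbest && std::abs(j - center) < std::abs(rowbestj - center)))
        { rowbest = Hv; rowbestj = j; }
      if (Hv > best && (global_mode ? (t == n && j == m) : true)) {
        best = Hv; bt = t; bj = j;
      }
    }
    if (!any) break;
    bestcol = rowbestj;
    center_prev = center;
  }

  IntegerVector centers(n + 1);
  for (int t = 0; t <= n; ++t) centers[t] = B.off[t] + w;
  List diag = List::create(_["live_cells"] = (double)live,
                           _["holes"] = (double)holes,
                           _["min_report_score"] = min_report_score,
                           _["band_width"] = B.width,
                           _["centers"] = centers);
  if (global_mode) {
    if (!B.inband(n, m) || B.H[B.at(n, m)] <= NEG)
      return List::create(_["passed"] = false, _["score"] = NA_INTEGER,
                          _["reason"] = "global endpoint outside band",
                          _["diagnostics"] = diag);
    best = B.H[B.at(n, m)];
    bt = n; bj = m;
  }
  if (!global_mode && best <= 0)
    return List::create(_["passed"] = false, _["score"] = 0,
                        _["reason"] = "no positive-scoring cell",
                        _["diagnostics"] = diag);

  // traceback over live cells from the best cell
  std::string ops;
  int t = bt, j = bj, state = 0; // 0=H,1=E,2=F
  int nm = 0, nx = 0, ni = 0, nd = 0;
  for (;;) {
    if (!B.inband(t, j) || (state == 0 && B.H[B.at(t, j)] <= NEG))
      stop("traceback entered a dead cell (internal consistency error)");
    uint8_t b = B.tb[B.at(t, j)];
    if (state == 0) {
      int src = b & 3;
      if (src == 0) break; // local start (or global origin)
      if (src == 1) {
        ops.push_back((b & 4) ? 'M' : 'X');
        if (b & 4) nm++; else nx++;
        t--; j--;
      } else if (src == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // E: consumed ref base j by a gap
      ops.push_back('D');
      nd++;
      bool ext = (b & 8) != 0;
      j--;
      state = ext ? 1 : 0;
    } else { // F: consumed read base t by a gap
      ops.push_back('I');
      ni++;
      bool ext = (b & 16) != 0;
      t--;
      state = ext ? 2 : 0;
    }
    if (t == 0 && j == 0 && global_mode) break;
  }
  std::reverse(ops.begin(), ops.end());

  // reported score must equal the additive sum over the trajectory
  long long recomputed = 0;
  {
    bool ingap = false;
    char gapch = 0;
    for (char o : ops) {
      if (o == 'M') { recomputed += match; ingap = false; }
      else if (o == 'X') { recomputed += mismatch; ingap = false; }
      else {
        if (!ingap || gapch != o) recomputed += gap_open + gap_ext;
        else recomputed += gap_ext;
        ingap = true; gapch = o;
      }
    }
  }

  // CIGAR: M spans match+mismatch columns
  std::string cigar;
  {
    char prev = 0;
    int run = 0;
    for (char o : ops) {
      char c = (o == 'M' || o == 'X') ? 'M' : o;
      if (c == prev) { run++; continue; }
      if (prev) cigar += std::to_string(run) + prev;
      prev = c; run = 1;
    }
    if (prev) cigar += std::to_string(run) + prev;
  }

  int read_span = bt - t;
  int cols_err = nx + ni + nd, cols_all = nm + nx + ni + nd;
  bool passed = best >= min_report_score && read_span >= min_len &&
                (cols_all > 0 && (double)cols_err <= a * cols_all);
  return List::create(
      _["passed"] = passed, _["score"] = best,
      _["score_recomputed"] = (double)recomputed,
      _["read_start"] = rs + t, _["read_end"] = rs + bt,
      _["ref_start"] = qs + j, _["ref_end"] = qs + bj,
      _["ops"] = ops, _["cigar"] = cigar, _["n_match"] = nm,
      _["n_mismatch"] = nx, _["n_ins"] = ni, _["n_del"] = nd,
      _["diagnostics"] = diag);
}
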