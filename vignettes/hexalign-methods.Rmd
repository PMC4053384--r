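---
title: "hexalign: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hexalign: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hexalign)
```

## The problem and the scoring model

Given a set of reference genomes $1 \dots r \dots N$ with sizes $G_r$ and
cumulative size $R = \sum G_r$, and a set of short reads $1 \dots s \dots S$
of length $L$, an alignment $A(s,r)$ is an ordered correspondence between
read letters and reference letters built from matches, mismatches,
insertions and deletions. Each operation carries an additive scoring
parameter, and the score of an alignment is the sum

$$SA(s,r) = \sum_l P_l ,$$

where $P_l$ is the match benefit, mismatch cost, or gap cost of the $l$-th
column. The task is to report, per read, an alignment maximizing $SA$.
Additive scoring is an explicit modelling assumption: dynamic-programming
optimality is relative to it, and a scheme in which, say, one triple
deletion is cheaper than three isolated single-base deletions is expressed
here only through the affine gap costs (a gap of $n$ bases costs
`gap_open` $+\,n\,\cdot$ `gap_extend`).

Exhaustive comparison is $O(S \times L \times R)$ and useless at modern
scales, so `hexalign` is a seed-and-extend aligner: exact $K$-mer seeds
nominate candidate positions, a cheap fuzzy extension filters and brackets
them, and only the surviving candidates reach the expensive
dynamic-programming stage. Around that core sit two read-space
optimizations — exact de-duplication with redundancy counts, and sorted
processing with cross-similarity reuse — that shrink the work per dataset
rather than per alignment.

## Pipeline overview

`run_pipeline()` executes, in order: read filtering (N policy), prefix-tree
non-redundification, sorted traversal, reference $K$-mer indexing
(recompiled per run), per-unique-read candidate lookup, fuzzy extension,
floating-band optimal alignment, and count-expanded reporting. Every stage
is deterministic; a fixed configuration and input give byte-identical SAM.

## Non-redundification and sorted order

Reads are inserted into a compressed prefix (Patricia) tree over the
alphabet A/C/G/T: sibling edges start with distinct bases and every
internal edge is the longest prefix common to its branch, so duplicate
detection costs one root-to-terminal walk and a new read causes at most
one edge split. Duplicates are discarded but counted: each unique sequence
carries a redundancy count and the original read ordinals it absorbed, so
downstream stages align each unique sequence once and expand results by
count afterwards.

Traversing the tree left-first (A before C before G before T, a
prefix-terminal before its extensions) visits every node once and emits
the unique reads in exact lexicographic order. Alongside the order we
record the *cross-similarity coefficient* $c_i$ of each read: the length
in bases of the longest common prefix with the immediately preceding read
in sorted order. The concept is a prefix-similarity degree; the LCP length
is this package's concrete definition of it. Sorted processing is
beneficial in itself (consecutive reads touch the same index regions,
which is cache-friendly) and $c_i$ powers the explicit cross-similarity
optimization below.

The read space can be split into $4^k$ disjoint classes by the 2-bit code
of the first $k$ bases (`partition_k`); per-class trees need no merge
step, and concatenating the per-class sorted outputs in class order equals
the single-tree order exactly (property-tested). Classes are processed
sequentially here; the partition exists for decomposition, not threading.
Reads shorter than $k$ are conceptually padded with `A` for class
assignment only.

## The k-mer index

References are compiled into a direct-addressed bucket table: a $K$-mer's
2-bit code (A=0, C=1, G=2, T=3, first base most significant, so code order
equals lexicographic order) *is* its bucket address. There is no hashing
and there are no collisions; the table has $4^K$ buckets and building it
is linear in $R$. Buckets hold (reference ordinal, position) pairs for
every `seed_step`-th N-free position. $K \le 14$ is enforced — the memory
footprint is $\sim 4^K + R$ integers — and longer configured seeds are
served by *double lookup*: a candidate requires two exact sub-$K$-mer
matches at read offsets `roff` and `roff + (seed_len - K)` on the same
diagonal, covering the full window.

In front of the table sits a presence bit vector with exactly one bit per
code — a degenerate, collision-free one-hash Bloom filter. A presence miss
proves the bucket empty (no false negatives), so the common miss case
costs one bit probe instead of a bucket fetch. The presence bit reflects
pre-masking occupancy.

Buckets whose occupancy exceeds the over-expression threshold
(`overexpression_threshold`, default 50 — the threshold concept is given,
the value is this package's choice) are *masked*: flagged, never deleted,
and skipped at lookup time. Over-expressed seeds are typical of
low-complexity regions and would otherwise flood the candidate list; a
read whose every seed is masked is reported unaligned with reason
`overexpressed_seeds`. An optional per-tile 2-mer entropy mask over the
reference (`ref_min_entropy`, off by default) is provided as an
interpretation of low-complexity reference masking.

Lookup walks the read's $K$-windows left to right, skips unindexable
(N-containing) windows, probes the presence bit, fetches surviving
buckets, and de-duplicates hits on (reference, diagonal), keeping the
leftmost read offset and a per-diagonal seed count. Candidates are then
ranked best-first by seed count and capped at `candidate_cap` (200) per
read and strand. On a random reference each $K$-mer has $\sim R/4^K$
occurrences, so shortening the seed by one base quadruples the candidate
load — the seed-length scaling the test suite reproduces empirically.

## Fuzzy extension: filter and bracket

Each surviving seed is extended bidirectionally by a small banded integer
DP (match $+1$, mismatch $-1$, gap open $-2$, gap extend $-1$; the paper's
stage is integer-arithmetic by design, the values are this package's
choice) in a floating window of half-width `window` (4) around the seed
diagonal, advancing one read base per front row.

Two deliberately loose *stop rules* terminate the front only in regions no
reportable alignment could cross: the error density over a trailing window
of `density_window` (32) rows exceeding $\max(2a, 0.5)$ — where $a$ is the
extension mismatch allowance — or the cumulative error count exceeding
$0.5\,t + 4$ at front row $t$. Early versions stopped at the allowance
itself; that filtered reads whose trimmed optimum was still reportable,
violating the filter-safety property below, and the looseness is the fix:
filtering is the job of the pass decision, not of the stop rule.

The *bracket* — the frame handed to the optimal aligner — is the full
front span on both sides, so trailing substitutions near a read end stay
inside the frame. The *pass decision* is evaluated on the score-argmax
prefix of each front, which trims edge mismatches exactly as a local
aligner would: the candidate passes when the trimmed extension length
reaches `ext_min_pct` (75%) of $L$ and its mismatch+indel count stays
within `ext_mismatch_pct` (15%) of the trimmed length, plus one mismatch
of slack. The thresholds are correlated with the optimal stage's on
purpose, and the slack makes the expensive stage, not the filter, the
final arbiter. The property the test suite enforces over $10^4$ seeded
random pairs: any pair whose full Smith-Waterman optimum (independent
oracle) meets the reporting thresholds must pass the filter — zero
violations.

Failed candidates carry a non-negative *margin*: the shortfall of the
extension score against the minimal passing score
$\lceil \text{min\_len} (1 - 2a) \rceil$. Margins feed the
cross-similarity skip rule.

## Optimal alignment: the floating, variable-width band

The reporting stage is local Smith-Waterman (Needleman-Wunsch sits behind
`mode = "global"`) with affine gaps, restricted per read row to a band of
half-width `band_width` (8) columns. The band is *floating*: its center
starts on the bracket's expected diagonal and drifts toward the column of
the previous row's maximum — the current highest-scoring path — by at most
one column per row beyond the diagonal advance. The drift cap is a
deliberate deviation from chasing the row maximum at full band speed: in
mismatch-rich rows the maximum bounces between near-tied columns, and a
fast-chasing center throws the true optimum out of the band; with the
one-column cap the band provably (property-tested against the full-matrix
oracle) recovers optima whose per-indel excursion fits the band, including
multi-indel trajectories whose *cumulative* excursion far exceeds the
half-width — the case a fixed diagonal band cannot handle.

Cells are *pruned* ("holes") when an admissible upper bound on any
completion through them — current cell score plus an all-match completion
of the remaining read — cannot reach the reporting threshold. In local
mode no distance-to-diagonal penalty is added to the bound: a local
alignment may end anywhere, so a forced-gap term would make the bound
inadmissible; the forced gap schedule applies only in global mode where
the path must reach the corner. Admissibility is what guarantees the
tested invariant that pruning changes which cells are computed, never the
reported result. The reporting threshold combines a minimal score
$\lceil m (M(1-a) + X a) \rceil$ (with $m$ = `min_match` = 36, $M$ = match,
$X$ = mismatch, $a$ = `mismatch_pct`/100; 132 at defaults), the minimal
aligned read length, and the mismatch+indel column fraction.

Storage is the linearized band — $\sim (2w+1) \times L$ cells with per-row
offsets — never the $L \times G_r$ rectangle; live-cell counts and hole
fractions are exposed as diagnostics. Traceback runs over live cells from
the maximal score, reconstructing the trajectory as M/X/I/D operations;
the reported score is re-derived from the trajectory under $\sum P_l$ and
asserted equal. Ties in score resolve to the first candidate encountered
in lookup order (and to the forward strand), making first-best reporting
deterministic.

## Explicit cross-similarity

Consecutive sorted reads share a prefix of $c$ bases, so their candidate
outcomes are correlated. With `cross_similarity = TRUE`, the extension
outcomes of the immediately preceding unique read (memo depth 1) are kept,
and a candidate at the same (reference, diagonal) is skipped iff the
previous read failed there with a margin exceeding the maximum score swing
the differing suffix could produce:

$$\text{margin} > (L - c) \cdot (\text{match} - \text{mismatch}) \cdot
\text{margin\_factor}$$

under the extension-stage scores. `margin_factor = Inf` provably skips
nothing (byte-identical output to the disabled run, tested). The option is
off by default: for references distant from the sample the prefix bound
is a heuristic economy, and the differential test requires only that at
the default margin fewer than 0.1% of reported alignments change on a
1%-error dataset. Only extension-stage failures are memoized; optimal-
stage failures are not.

## Read simulator

`simulate_reads()` emulates the artificial-read protocol used for
validation: uniform i.i.d. random references; reads cut at uniform random
offsets of uniformly chosen references (optionally restricted to a source
subset for mixture experiments, or to a few pre-drawn sites to emulate
heavily redundant datasets); per-base error probability $e \in \{0, 0.01,
0.05, \dots\}$ with errored positions split 0.9/0.05/0.05 between
substitutions, insertions and deletions (the protocol calls the errors
random without stating a composition; the split is configurable). Reads
are re-trimmed to length $L$ after indels, qualities are constant, and a
truth table records source, offset, strand and injected edit counts.
Identical configurations give byte-identical FASTQ.

What the simulator does *not* emulate — and therefore what passing tests
do not show about real data: quality-dependent and homopolymer error
profiles, coverage bias, real genome repeat and low-complexity structure,
contamination, and paired-end geometry. Synthetic uniform references make
seed statistics benign ($R/4^K$ occupancy); real eukaryotic references
stress the masking machinery much harder.

## Numerical and policy choices

* **Coordinates.** 0-based half-open everywhere internally and in result
  objects; SAM output is 1-based per the format.
* **Scoring defaults.** match $+5$, mismatch $-4$, gap open $-12$, gap
  extend $-2$: values chosen so the 15% mismatch allowance and minimum
  match length 36 are meaningful; the parameter set $P$ is named by the
  protocol, the values are not, and all are configurable.
* **N policy.** Reads with more than 10% N are dropped (counted as
  unaligned); other N-containing reads bypass the ACGT-only prefix tree as
  singleton uniques, their N-overlapping seed windows are unindexable, and
  N never matches during extension or alignment (scored as mismatch).
* **Strand.** The protocol never states strand handling; by default both
  the read and its reverse complement are aligned and the better score is
  reported (SAM flag 0x10, sequence reverse-complemented), with
  `strand = "forward"` available.
* **Percent unaligned** is computed over original (redundant) read counts,
  dropped reads included.
* **Ties.** Equal-score candidates: first in lookup order; equal across
  strands: forward. Row-maximum ties in the band: the column nearest the
  center.
* **Degenerate inputs.** Empty read sets produce header-only SAM and a
  zero summary; empty sequences, malformed FASTA/FASTQ and out-of-range
  seeds raise typed errors naming the offending record or line.

## Problem sizes used by the test and acceptance suites

The suites run entirely on simulated data, sized for a desk machine:
single-reference proof-of-concept runs use a 12 kb reference with 10,000
error-free 100-base reads; mixture separation uses 15 references of 10 kb
with reads from 2 of them; seed-length scaling uses a 1 Mb reference;
oracle-equivalence suites use 500 bracketed pairs against the full-matrix
Smith-Waterman of `Biostrings::pairwiseAlignment` (with a pure-R Gotoh as
a second oracle at tiny sizes); dedup equivalence uses $10^5$ reads
against a sort-and-count oracle. These sizes are the package's choice of
a convincing-yet-compact experimental design.

## Known limitations

* Single-end reads only; no mate flags, no spliced alignment, no
  quality-aware scoring.
* The direct-address table at $K = 14$ allocates $4^{14}$ bucket slots
  (~1 GB of counters) regardless of reference size; small-genome work can
  use a smaller $K$ at index level via double lookup, and
  `release_index()` frees the arrays eagerly.
* A single gap wider than the band half-width is recovered only lossily;
  widen `band_width` for indel-rich applications.
* The cross-similarity skip bound assumes the prefix-similarity model of
  sorted reads; it is intentionally off by default and not recommended for
  references distant from the sample.
* The repeat/transposition-aware search mode referenced alongside some
  published sensitivity figures is undescribed at the algorithm level and
  is out of scope here.
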