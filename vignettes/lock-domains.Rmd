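---
title: "Calling and comparing large organized chromatin lysine domains"
author: "lockscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and comparing large organized chromatin lysine domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lockscape)
```

## The problem

Histone post-translational modifications are usually analysed as individual
peaks ("individual elements"), but nearby peaks of the same modification
aggregate into much larger domains — large organized chromatin lysine (K)
domains, LOCKs. Broad-domain callers that work on raw ChIP-seq signal are
notoriously unstable for some marks; this package instead clusters the peak
calls themselves, so the only input a caller needs is a BED file of peaks.
Downstream, the package provides the comparative analyses that make LOCKs
biologically interesting: active-mark LOCKs cover far more of the genome in
primitive (ESC/iPSC-like) than in differentiated cells, LOCK localization
classifies samples by tissue and class, active LOCKs in primitive cells carry
repressive H3K27me3 signal (bivalency), and those bivalent domains sit at TAD
boundaries bound by regulators of chromatin interactions (CTCF, RAD21,
ZNF143, but not YY1).

## The domain-calling model

All interval arithmetic is 0-based half-open on disk (BED convention) and
GRanges-based in memory. Input peaks are merged at load time so the caller
sees disjoint elements; the gap between consecutive peaks is
`next.start - prev.end` (book-ended peaks have gap 0).

A candidate domain of *Order* O is a run of O consecutive peaks on one
chromosome; its *window size* is the largest internal gap. The caller works
in six steps:

1. For each Order, collect the window-size distribution over all runs.
2. Estimate a per-Order *stitching distance* threshold from that
   distribution.
3. Determine the maximum Order attested by the data.
4. Scan each chromosome from the highest Order down, left to right, claiming
   any run of unassigned peaks whose window size is at or below the Order's
   threshold.
5. Discard low-Order domains whose largest gap lies within
   `near_threshold_epsilon` (default 10%) of their Order's threshold —
   borderline stitches of Order at most `low_order_cutoff` (default 3) are
   more likely background coincidences than domains.
6. Iterate steps 4–5 with the minimum included Order lowered from the
   maximum Order toward 2, tracking the *relative sum* — the fraction of the
   called domains' span covered by their member peaks. The iteration stops
   when the relative sum starts oscillating; the last stable domain set is
   returned.

### The stitching threshold (knee rule)

When peaks really do cluster, inter-peak gaps are bimodal: tight
intra-domain gaps versus background gaps orders of magnitude larger. The
default threshold estimator sorts an Order's window sizes ascending, takes
`log10(x + 1)`, and returns the value with the largest perpendicular
distance *below* the chord joining the first and last points. Restricting to
points below the chord is the standard elbow convention for an ascending
convex curve, and it matters here: with the unsigned distance, whenever
tight windows are a minority the knee flips to the opposite shoulder of the
step — the first background-scale value — and the threshold then licenses
stitching across background gaps. The below-chord knee lands on the largest
tight window whenever a tight mode exists, degrades to the smallest window
when every point hugs the chord, and returns the common value for a
constant distribution.

A quantile rule (`threshold_rule = "quantile"`) is available as an
alternative; it uses the inverse-ECDF (type 1) quantile so that, like the
knee, it always returns an attained window size.

### Attesting the maximum Order

An Order is attested when at least `min_candidate_windows` (default 2)
windows fall at or below its threshold — a maximum Order witnessed by a
single window is fragile — *and* its threshold stays within
`mode_separation` (default 2) times the order-2 threshold. The second
condition is what keeps the caller honest at high Orders: once runs of an
Order can only be formed by swallowing background gaps, every window shares
the same large maximum gap, the window distribution collapses to a single
mode, and any within-distribution estimator will happily return a
background-scale "threshold". Anchoring admissibility to the order-2 knee
(the global gap landscape) rejects those Orders. For an exactly uniform gap
structure the two thresholds coincide at every Order, so the maximum Order
is the longest same-chromosome run — the degenerate case behaves as
expected. The same scale guard is applied to every per-Order threshold used
during clustering, because with heavy-tailed background gaps the knee chord
can land inside the background mode for intermediate Orders where tight
windows are rare.

### The stopping rule

Lowering the minimum included Order monotonically adds smaller domains, and
the relative sum drifts as it does; with few domains at the top Orders the
first steps routinely move it by well over 5%. A drift is not an
oscillation. The caller therefore stops only when the relative-sum
difference *reverses direction* with a relative magnitude above
`oscillation_limit` (default 5%) — the signature of the statistic starting
to oscillate — and returns the domain set from before the reversal. If no
reversal occurs the final (`o_min = 2`) set is returned. The full trace is
kept in `$relative_sum_trace` for inspection.

Peaks released by the step-5 filter are not re-clustered within the same
iteration, which keeps each iteration a pure function of the peak set and
the minimum Order.

## Downstream analyses

* **Coverage comparison** — per-sample genomic coverage of LOCK spans and of
  individual elements; groups compared by the ratio of medians and a
  two-sided rank test, BH-corrected across all mark × feature tests in the
  run. The test is exact for small samples without ties, otherwise the
  normal approximation with continuity and tie correction. Between-group
  comparisons use the unpaired rank-sum form; the paired signed-rank form
  exists behind `paired = TRUE` (a signed-rank test requires pairing, which
  unpaired groups of cell types do not have).
* **Classification** — sample similarity is the base-pair Jaccard of two
  samples' LOCK sets (a presence-vector Jaccard over the merged catalogue is
  available via `method = "presence"`); prediction is 1-nearest-neighbour
  under leave-one-out, ties to the smallest sample index; scoring is
  one-vs-rest MCC, macro-averaged. A label-permutation helper re-predicts
  with permuted labels over the fixed similarity structure.
* **Catalogue and tissue assignment** — cross-sample union-merged regions
  with a binary presence matrix; a region belongs to a tissue when present
  in strictly more than half of that tissue's samples.
* **Gene association** — a gene is associated with a region when its TSS
  lies within 10 kb (inclusive) of the region, distance 0 inside, otherwise
  the distance to the nearest covered base; strand is ignored. The
  convention is fixed and testable; distances are checked against an
  all-pairs scan.
* **Bivalency** — the repressive track is integrated over each active-mark
  LOCK (signal × overlapped bp), divided by the LOCK length, then divided by
  the median per-bp signal of the individual elements of the same profile;
  the score is invariant to global rescaling of the track. LOCKs are split
  into high/intermediate/low by tertiles (the category boundaries are not
  externally defined; tertiles are the package's convention), ties broken by
  region order, with high and low counts differing by at most one. The
  cross-cell-line matrix divides the per-LOCK signal by track depth
  (total signal × bp) and LOCK length, takes the median over LOCKs, and
  normalizes each mark's row by its maximum.
* **Enrichment** — upper-tail hypergeometric tests with explicit custom
  backgrounds: gene sets against the individual-element gene catalogue;
  LOCK signal categories at TAD boundaries (at-boundary = edge-to-edge
  distance ≤ 10 kb, background = all LOCKs); and regulator binding sites as
  a bp-weighted urn (population = LOCK bp, successes = sites in LOCKs,
  query = category bp) — the size normalization the analysis calls for is
  absorbed into the null rather than applied to the counts, which keeps the
  test well defined. BH families are one per analysis type per run.

## The synthetic cohort generator

Every stage is exercised against a generator that plants the structure the
analyses are designed to detect, with the planted truth returned alongside
the files. What it emulates, and how:

* **Bimodal gap structure** — clusters of 8–25 peaks (peak length ~N(800,
  150) bp clamped to [300, 1200]; intra-cluster gaps ~N(1200, 400) clamped
  to [1, 2000]) separated by background gaps ~N(60 kb, 15 kb) clamped to
  [20 kb, 120 kb], plus unclustered singleton peaks. Clamping makes the two
  gap modes provably separable, which is what the caller needs — realism of
  the tails is not the point.
* **Shared localization** — cluster positions come from a fixed per-mark
  grid of slots (25 per 3 Mb chromosome, two chromosomes); each tissue owns
  a slot pool and each sample draws its clusters from its tissue's pool, so
  tissue-mates share domain locations and the Jaccard classifier has
  structure to find.
* **Class-dependent coverage** — primitive samples plant 30 active-mark
  clusters, differentiated samples 30/`coverage_fold_primitive` (default
  fold 3); repressive marks plant 20 in both classes (fold 1).
* **Bivalency** — 30% of the primitive H3K4me1 slot pool is bivalent;
  those clusters receive H3K27me3 signal at 3.5× background in 2 kb
  bedGraph bins (5% multiplicative noise). With fewer than a third of
  elements elevated, the element median stays at background and the
  normalized score of bivalent LOCKs sits near the planted fold.
* **TAD boundaries** — planted as points within 8 kb of bivalent slots with
  probability `boundary_bias` (default 0.9), plus background boundaries at
  least 20 kb from any slot.
* **Regulators** — CTCF/RAD21/ZNF143 analogs concentrate 5 sites inside
  each bivalent slot plus genome-wide background sites; the YY1 analog is
  uniform genome-wide.
* **Expression** — genes cluster near slots (plus scattered background
  genes); a gene's expression in a sample is suppressed 5× when its TSS
  lies within 10 kb of one of that sample's bivalent clusters.
* **Transition** — in differentiated samples the H3K9me3 track is elevated
  over the (former) bivalent slots, so the cross-cell-line matrix recovers
  the bivalent-to-repressive switch.

Randomness is a single seed with fixed per-stream offsets (cohort-level
structures and each sample × mark get their own substream), so adding
samples never reshuffles existing ones and identical seeds give
byte-identical files.

Problem sizes are deliberately desk-scale: two 3 Mb chromosomes, 16 samples,
four marks — enough for every planted effect to be detected at conventional
significance, small enough that the whole workflow (and its five-seed
recovery check) runs in minutes.

What the generator does **not** emulate: mappability artifacts or read-level
noise; peak-calling uncertainty (peaks are planted exactly); realistic
chromatin biology of domain shapes; and, notably, the observation on real
epigenomes that individual-element coverage is similar across classes while
LOCK coverage is not — matching element counts across classes at
non-stitchable spacing does not fit a 6 Mb genome, so in the synthetic
cohort element coverage scales with cluster count. Passing tests show the
pipeline recovers planted structure of this kind; they do not certify
performance on real ChIP-seq peak sets.

## Numerical and design choices

* Thresholds are always attained window sizes, so admissibility (`<=`) is
  exact in integer coordinates; no floating-point boundary cases arise.
* Greedy conflict resolution is higher Order first, then chromosome, then
  leftmost; deterministic, and checked against exhaustive enumeration on
  small peak sets.
* The caller contains no randomness; identical inputs give identical
  output.
* Degenerate inputs: fewer than two peaks give an empty domain set with an
  empty trace; an empty LOCK set has an undefined relative sum (`NA`), which
  the driver records without comparing; fully tied rank-test data give
  p = 1 with a degenerate flag; a zero median in a fold-change denominator
  is reported as infinite with a flag rather than an error.
* Tertile ties are broken by region order; with all-equal scores the split
  is still deterministic and balanced.
* `dhyper`-family tails are computed in log space (`phyper(..., log.p =
  TRUE)`), exponentiated once.

## Limitations

* The per-Order threshold estimator and the exact quantity varied across
  the caller's outer iterations are conventions of this package (knee rule;
  minimum included Order); other choices are defensible, which is why both
  are parameters.
* The regulator urn treats every LOCK base pair as exchangeable; real
  binding-site placement is not uniform even under the null.
* With a single sample in a class, leave-one-out prediction of that class
  is impossible; the classifier warns and scores anyway.
* The generator's clamped-normal gaps make mode separation essentially
  certain; real data can present overlapping gap modes, where the knee
  threshold and the `mode_separation` guard become conservative (fewer,
  smaller domains).

## Running the workflow

```{r, eval = FALSE}
truth <- simulate_cohort(sim_config(seed = 1), "cohort")
cohort <- load_cohort("cohort")
locks <- call_cohort_locks(cohort)
reports <- classify_cohort(locks, cohort$metadata)
cmp <- compare_groups(cohort_coverage(locks), cohort$metadata)
```

or, end to end with a manifest:

```{r, eval = FALSE}
run_pipeline(list(seed = 1), "run1")
```

The numbered scripts under `analysis/` run the same stages as a narrative
sequence and write their tables under `results/`.
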