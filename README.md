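# lockscape

Calling and comparative analysis of **large organized chromatin lysine (K)
domains (LOCKs)** — broad genomic domains formed by clusters of nearby
histone-modification peaks — and of the downstream signatures that
discriminate primitive (ESC/iPSC-like) from differentiated cell
populations.

## Who this is for

Epigenomics analysts who have per-sample peak calls (BED) for histone marks
such as H3K4me1, H3K27ac, H3K27me3 or H3K9me3 and want to: call broad
domains from the peaks rather than from noisy signal tracks; compare domain
coverage between sample groups; classify samples by domain localization;
score bivalency (repressive H3K27me3 signal over active-mark domains); and
test whether domain categories concentrate at TAD boundaries or are bound
by regulators of chromatin interactions (CTCF, RAD21, ZNF143, YY1).

## The method

**Domain calling.** A candidate domain of *Order* O is a run of O
consecutive peaks on one chromosome; its *window size* is its largest
internal gap (gap = next start − previous end, 0-based half-open). For each
Order the caller estimates a *stitching distance* threshold as the knee of
the sorted, log10-scaled window-size distribution (the point farthest below
the chord), determines the largest Order attested by at least 2
threshold-admissible windows on the intra-domain gap scale, then scans each
chromosome from the highest Order down, left to right, claiming admissible
runs of unassigned peaks. Low-Order domains whose largest gap lies within
10% of their threshold are filtered. The procedure iterates with the
minimum included Order lowered toward 2, tracking the *relative sum*

    RS = (bp of member peaks) / (bp spanned by the called domains),

and stops when RS starts oscillating (direction reversal > 5%), returning
the last stable domain set.

**Downstream.** Genomic-coverage comparison between classes (ratio of
medians, two-sided rank-sum test, Benjamini–Hochberg correction across all
mark × feature tests); 1-nearest-neighbour leave-one-out classification on
base-pair Jaccard similarity of domain sets, scored by macro-averaged
Matthews correlation coefficient (MCC); bivalency scoring of tracks over
domains normalized to the individual elements of the same profile, with
high/intermediate/low tertile categories; TSS-anchored gene association
(≤ 10 kb); and upper-tail hypergeometric enrichment with explicit custom
backgrounds (gene sets vs the individual-element gene catalogue, domain
categories at TAD boundaries vs all domains, regulator binding as a
bp-weighted urn).

A fully synthetic cohort generator plants all of these structures with
known truth, so the entire workflow is testable offline; see the methods
vignette (`vignettes/lock-domains.Rmd`) for the model, parameter and design
discussion.

## Worked example

```r
library(lockscape)

truth  <- simulate_cohort(sim_config(seed = 1), "cohort")   # 16 samples x 4 marks
cohort <- load_cohort("cohort")

pf    <- cohort$peak_files
peaks <- read_bed(pf$path[pf$sample_id == "prim_ESC_1" & pf$mark == "H3K4me1"],
                  merge = TRUE)
length(peaks)
#> [1] 515

locks <- call_locks(peaks, sample_id = "prim_ESC_1", mark = "H3K4me1")
locks
#> lock_set: 40 LOCKs (prim_ESC_1, H3K4me1)
#>   span: 910,706 bp; Orders 3 - 16
#>   iterations: 15 ; final relative sum: 0.4223

head(locks$relative_sum_trace, 3)
#>   iteration o_min n_locks relative_sum
#> 1         1    16      15    0.4162462
#> 2         2    15      18    0.4130582
#> 3         3    14      19    0.4132309

unlist(bp_f1(locks$locks, truth_granges(truth, "prim_ESC_1", "H3K4me1")))
#> precision    recall        f1
#> 1.0000000 0.9774387 0.9885906
```

The 515 peaks collapse into 40 domains of Order 3–16 spanning 0.91 Mbp;
roughly 42% of the spanned base pairs are peak-covered (the relative sum),
and the called domains match the planted clusters at bp-F1 0.989 (every
called base pair lies in a planted domain; the small recall loss is the
inter-peak gaps at run boundaries).

The numbered scripts under `analysis/` run the full study as a narrative
sequence — `01_simulate.R` through `07_enrichment.R` — each a thin driver
over the package functions, writing its tables under `results/`. The same
stages can be run as one reproducible unit with a manifest:

```r
run_pipeline(list(seed = 1), "run1")
```

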