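# A reduced configuration keeps generator unit tests fast; gap and signal
# distributions stay at their default values.
small_cfg <- function(seed = 1L, ...) {
  sim_config(n_samples_per_class = list(primitive = 2L, differentiated = 2L),
             tissues = list(primitive = "ESC", differentiated = "blood"),
             marks = c(H3K4me1 = "active", H3K27me3 = "repressive"),
             seed = seed, ...)
}

test_that("identical seeds give byte-identical cohorts", {
  d1 <- file.path(tempdir(), "sim-det-1"); d2 <- file.path(tempdir(), "sim-det-2")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_cohort(small_cfg(seed = 5L), d1)
  simulate_cohort(small_cfg(seed = 5L), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_equal(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("planted primitive/differentiated coverage ratio is near the target fold", {
  sc <- shared_cohort()
  tr <- truth_report(sc$truth)
  md <- sc$truth$metadata
  for (m in c("H3K4me1", "H3K27ac")) {
    bp <- tr$planted_bp[tr$mark == m]
    cls <- md$class[match(tr$sample_id[tr$mark == m], md$sample_id)]
    ratio <- sum(bp[cls == "primitive"]) / sum(bp[cls == "differentiated"])
    expect_gte(ratio, 2.4); expect_lte(ratio, 3.6)
  }
})

test_that("zero bivalent fraction leaves repressive signal flat over active clusters", {
  d <- file.path(tempdir(), "sim-nobiv")
  unlink(d, recursive = TRUE)
  truth <- simulate_cohort(small_cfg(seed = 6L, bivalent_fraction = 0), d)
  sid <- truth$metadata$sample_id[truth$metadata$class == "primitive"][1]
  track <- read_bedgraph(truth$files$signal[[paste0(sid, "__H3K27me3")]])
  cl <- truth$clusters[truth$clusters$sample_id == sid &
                         truth$clusters$mark == "H3K4me1", ]
  spans <- gr0(cl$chrom, cl$start, cl$end)
  ov <- signal_over_intervals(track, spans)
  cfg <- truth$config
  expect_lte(mean(ov$per_bp), 1.5 * cfg$background_signal)
})

test_that("truth report row counts and coverage sums are consistent", {
  sc <- shared_cohort()
  tr <- truth_report(sc$truth)
  cl <- sc$truth$clusters
  expect_equal(sum(tr$n_clusters), nrow(cl))
  expect_equal(sum(tr$planted_bp), sum(cl$end - cl$start))
  one <- tr[tr$sample_id == tr$sample_id[1] & tr$mark == tr$mark[1], ]
  sub <- cl[cl$sample_id == one$sample_id & cl$mark == one$mark, ]
  expect_equal(one$planted_bp, sum(sub$end - sub$start))
})

test_that("emitted peak files are disjoint (no merge events on load)", {
  sc <- shared_cohort()
  pf <- sc$cohort$peak_files
  for (r in sample(nrow(pf), 6)) {
    raw <- read_bed(pf$path[r], merge = FALSE)
    merged <- read_bed(pf$path[r], merge = TRUE)
    expect_equal(length(raw), length(merged))
  }
})

test_that("intra-cluster and background gap modes are separable across seeds", {
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed)
    .lockscape_env <- asNamespace("lockscape")
    set.seed(seed)
    intra <- get(".tnorm", .lockscape_env)(500, cfg$intra_cluster_gap)
    bg <- get(".tnorm", .lockscape_env)(500, cfg$background_gap)
    expect_lt(max(intra), min(bg))
  }
})

test_that("infeasible packing is rejected before any file is written", {
  d <- file.path(tempdir(), "sim-infeasible")
  unlink(d, recursive = TRUE)
  cfg <- small_cfg(seed = 7L)
  cfg$chrom_length <- 2e5  # slots cannot hold a maximal cluster
  expect_error(simulate_cohort(cfg, d), "infeasible packing")
  expect_false(dir.exists(d))
})
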