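# The caller's six components: window-size distributions, stitching
# thresholds, maximum Order, greedy clustering, the near-threshold filter,
# the relative sum, and the iterative driver.

test_that("window sizes are the max gap per run of consecutive peaks", {
  pk <- gr0("chr1", c(0, 20, 100, 120), c(10, 30, 110, 130))
  expect_equal(window_size_distribution(pk, 2), c(10, 70, 10))
  expect_equal(window_size_distribution(pk, 4), 70)
  expect_equal(window_size_distribution(pk, 5), numeric(0))
  expect_error(window_size_distribution(pk, 1), "order")
})

test_that("window runs never span chromosomes", {
  pk <- gr0(c("chr1", "chr1", "chr2", "chr2"),
            c(0, 20, 0, 50), c(10, 30, 40, 60))
  expect_equal(window_size_distribution(pk, 2), c(10, 10))
})

test_that("stitching threshold: knee and quantile rules", {
  expect_equal(stitching_threshold(c(10, 10, 70)), 10)
  expect_equal(stitching_threshold(c(50, 50, 50)), 50)
  expect_equal(stitching_threshold(1:100, rule = "quantile", q = 0.25), 25)
  expect_true(is.na(stitching_threshold(numeric(0))))
  # threshold is always an attained window size
  set.seed(1)
  for (i in 1:20) {
    ws <- sample(c(sample(10:100, 5), sample(5000:9000, 12)))
    expect_true(stitching_threshold(ws) %in% ws)
  }
})

test_that("max_order finds planted cluster order and degenerate cases", {
  # two planted 10-peak clusters (intra-gap 100 bp) in a 100 kb background
  starts <- c(seq(0, by = 110, length.out = 10),
              seq(1e5, by = 110, length.out = 10))
  pk <- gr0("chr1", starts, starts + 10)
  expect_gte(max_order(pk), 10)

  # exactly uniform gaps: the threshold admits every window, so the maximum
  # Order is bounded only by the candidate-window requirement: the longest
  # run when a single witness window suffices, one less under the default
  # two-window requirement
  u <- seq(0, by = 100, length.out = 8)
  expect_equal(max_order(gr0("chr1", u, u + 50),
                         caller_params(min_candidate_windows = 1)), 8L)
  expect_equal(max_order(gr0("chr1", u, u + 50)), 7L)

  # a single peak per chromosome
  expect_equal(max_order(gr0(c("chr1", "chr2"), c(0, 0), c(10, 10))), 1L)
})

test_that("cluster_peaks claims admissible runs greedily", {
  pk <- gr0("chr1", c(0, 20, 40), c(10, 30, 50))
  ls <- cluster_peaks(pk, c(`3` = 10), o_min = 3)
  expect_equal(length(ls$locks), 1L)
  expect_equal(GenomicRanges::start(ls$locks), 1L)
  expect_equal(GenomicRanges::end(ls$locks), 50L)
  expect_equal(S4Vectors::mcols(ls$locks)$order, 3)

  # order 3 inadmissible, order 2 stitches leftmost pair only; the middle
  # peak is then assigned, so the second pair cannot form
  ls <- cluster_peaks(pk, c(`3` = 5, `2` = 10), o_min = 2)
  expect_equal(length(ls$locks), 1L)
  expect_equal(GenomicRanges::end(ls$locks), 30L)

  # nothing admissible
  ls <- cluster_peaks(pk, c(`3` = 1, `2` = 1), o_min = 2)
  expect_equal(length(ls$locks), 0L)
  expect_error(cluster_peaks(pk, c(`2` = 10), o_min = 1), "o_min")
})

test_that("near-threshold filter drops only low-Order LOCKs close to their threshold", {
  mk <- function(starts, widths = 10) gr0("chr1", starts, starts + widths)
  params <- caller_params()
  # order 2, max_gap 95, threshold 100 -> removed (95 > 90)
  pk <- mk(c(0, 105))
  ls <- cluster_peaks(pk, c(`2` = 100), o_min = 2, params = params)
  expect_equal(length(filter_near_threshold(ls, params)$locks), 0L)
  # order 2, max_gap 50 -> retained
  pk <- mk(c(0, 60))
  ls <- cluster_peaks(pk, c(`2` = 100), o_min = 2, params = params)
  expect_equal(length(filter_near_threshold(ls, params)$locks), 1L)
  # order 10 (above cutoff), gap at threshold -> retained
  pk <- mk(seq(0, by = 110, length.out = 10))
  ls <- cluster_peaks(pk, c(`10` = 100), o_min = 10, params = params)
  expect_equal(length(filter_near_threshold(ls, params)$locks), 1L)
})

test_that("relative sum is peak bp over LOCK-span bp", {
  # one LOCK [0,100) containing peaks covering 60 bp
  pk <- gr0("chr1", c(0, 70), c(30, 100))
  ls <- cluster_peaks(pk, c(`2` = 100), o_min = 2)
  expect_equal(relative_sum(ls, pk), 0.6)

  # two LOCKs: spans 100 and 60 bp, member peaks 50 and 50 bp; numerators
  # and denominators are summed over LOCKs before dividing
  pk <- gr0("chr1", c(0, 80, 200, 230), c(30, 100, 220, 260))
  ls <- cluster_peaks(pk, c(`2` = 200), o_min = 2)
  expect_equal(length(ls$locks), 2L)
  expect_equal(relative_sum(ls, pk), (50 + 50) / (100 + 60))

  # a LOCK whose span is almost fully covered by its member peaks
  pk <- gr0("chr1", c(0, 11), c(10, 21))
  ls <- cluster_peaks(pk, c(`2` = 1), o_min = 2)
  expect_equal(relative_sum(ls, pk), 20 / 21)

  empty <- cluster_peaks(pk, c(`2` = -1), o_min = 2)
  expect_true(is.na(relative_sum(empty, pk)))
})

test_that("call_locks recovers a single dense cluster and is deterministic", {
  starts <- c(seq(0, by = 120, length.out = 12), 5e5, 9e5)
  pk <- gr0("chr1", starts, starts + 20)
  # with a single witness window allowed, the cluster is claimed whole
  ls_full <- call_locks(pk, caller_params(min_candidate_windows = 1))
  expect_equal(length(ls_full$locks), 1L)
  expect_equal(GenomicRanges::start(ls_full$locks), 1L)
  expect_equal(GenomicRanges::end(ls_full$locks), starts[12] + 20)
  # under the default two-window requirement the top Order is one less and
  # the last peak remains unclustered
  ls <- call_locks(pk)
  expect_gte(nrow(ls$relative_sum_trace), 1L)
  expect_equal(length(ls$locks), 1L)
  expect_equal(GenomicRanges::start(ls$locks), 1L)
  expect_equal(GenomicRanges::end(ls$locks), starts[11] + 20)

  ls2 <- call_locks(pk)
  expect_identical(ls$locks, ls2$locks)
  expect_identical(ls$relative_sum_trace, ls2$relative_sum_trace)

  # fewer than 2 peaks: empty set, empty trace
  ls <- call_locks(gr0("chr1", 0, 10))
  expect_equal(length(ls$locks), 0L)
  expect_equal(nrow(ls$relative_sum_trace), 0L)
})

test_that("every called LOCK satisfies its Order's gap admissibility and LOCK invariants", {
  set.seed(3)
  for (rep in 1:5) {
    df <- random_peaks(60)
    pk <- gr0(df$chrom, df$start, df$end)
    ls <- call_locks(pk)
    if (length(ls$locks) == 0L) next
    ord <- S4Vectors::mcols(ls$locks)$order
    gap <- S4Vectors::mcols(ls$locks)$max_gap
    thr <- ls$thresholds[as.character(ord)]
    expect_true(all(gap <= thr))
    expect_true(all(ord >= 2))
    # non-overlapping locks, disjoint members, members within input peaks
    expect_equal(length(GenomicRanges::reduce(ls$locks)), length(ls$locks))
    mem <- unlist(ls$members)
    expect_equal(anyDuplicated(mem), 0L)
    expect_true(all(mem >= 1 & mem <= length(pk)))
    # relative sums in (0, 1]
    rs <- ls$relative_sum_trace$relative_sum
    expect_true(all(rs > 0 & rs <= 1, na.rm = TRUE))
  }
})

test_that("clustering is scale-equivariant in coordinates and thresholds", {
  df <- data.frame(start = c(0, 30, 60, 500, 530),
                   end = c(10, 40, 70, 510, 540))
  k <- 7
  a <- cluster_peaks(gr0("chr1", df$start, df$end), c(`3` = 25, `2` = 25), 2)
  b <- cluster_peaks(gr0("chr1", df$start * k, df$end * k),
                     c(`3` = 25 * k, `2` = 25 * k), 2)
  expect_equal(GenomicRanges::start(b$locks) - 1L,
               (GenomicRanges::start(a$locks) - 1L) * k)
  expect_equal(GenomicRanges::end(b$locks), GenomicRanges::end(a$locks) * k)
  expect_equal(S4Vectors::mcols(b$locks)$order, S4Vectors::mcols(a$locks)$order)
})

test_that("uniform-gap peaks give one near-chromosome LOCK with a monotone trace", {
  u <- seq(0, by = 1000, length.out = 40)
  pk <- gr0("chr1", u, u + 200)
  ls <- call_locks(pk)
  expect_equal(length(ls$locks), 1L)
  rs <- ls$relative_sum_trace$relative_sum
  expect_true(all(diff(rs) >= 0) || all(diff(rs) <= 0))
})
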