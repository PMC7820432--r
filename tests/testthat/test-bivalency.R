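mk_track <- function(start, end, value, chrom = "chr1") {
  signal_track(gr0(chrom, start, end), value)
}

test_that("signal integrals follow bedGraph semantics", {
  tr <- mk_track(0, 100, 2.0)
  ov <- signal_over_intervals(tr, gr0("chr1", 0, 50))
  expect_equal(ov$raw, 100)
  expect_equal(ov$per_bp, 2.0)

  tr <- mk_track(c(0, 50), c(50, 100), c(1, 3))
  ov <- signal_over_intervals(tr, gr0("chr1", 25, 75))
  expect_equal(ov$raw, 25 + 75)
  expect_equal(ov$per_bp, 2.0)

  ov <- signal_over_intervals(tr, gr0("chr1", 500, 600))
  expect_equal(ov$raw, 0)
  expect_warning(signal_over_intervals(tr, gr0("chr9", 0, 10)), "absent")
})

test_that("signal integral is additive under region splitting", {
  set.seed(41)
  for (i in 1:10) {
    n <- 6
    bounds <- sort(sample(0:2000, n + 1))
    tr <- mk_track(bounds[-(n + 1)], bounds[-1], round(runif(n, 0, 5), 2))
    a <- sample(0:900, 1); c_ <- a + sample(200:1000, 1); b <- a + sample(100:(c_ - a - 1), 1)
    r_ac <- signal_over_intervals(tr, gr0("chr1", a, c_))$raw
    r_ab <- signal_over_intervals(tr, gr0("chr1", a, b))$raw
    r_bc <- signal_over_intervals(tr, gr0("chr1", b, c_))$raw
    expect_equal(r_ac, r_ab + r_bc)
  }
})

test_that("signal integrals agree with per-base brute force", {
  set.seed(43)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    bounds <- sort(sample(0:10000, 2 * n))
    s <- bounds[seq(1, 2 * n, 2)]; e <- bounds[seq(2, 2 * n, 2)]
    v <- round(runif(n, 0, 4), 3)
    tr <- mk_track(s, e, v)
    rs <- sample(0:9000, 1); re <- rs + sample(100:1000, 1)
    got <- signal_over_intervals(tr, gr0("chr1", rs, re))$raw
    expect_equal(got, oracle_signal_raw(s, e, v, rs, re))
  }
})

test_that("normalization to individual elements is scale invariant", {
  locks <- data.frame(region_id = "L1", width = 100, raw = 400, per_bp = 4.0)
  elems <- data.frame(region_id = c("e1", "e2", "e3"), width = 10,
                      raw = c(15, 20, 25), per_bp = c(1.5, 2.0, 2.5))
  out <- normalize_to_individual(locks, elems)
  expect_equal(out$normalized, 2.0)
  # scaling the track by 10 scales both numerator and denominator
  locks10 <- locks; locks10$raw <- locks$raw * 10; locks10$per_bp <- locks$per_bp * 10
  elems10 <- elems; elems10$raw <- elems$raw * 10; elems10$per_bp <- elems$per_bp * 10
  expect_equal(normalize_to_individual(locks10, elems10)$normalized, 2.0)

  elems0 <- elems; elems0$per_bp <- 0
  expect_error(normalize_to_individual(locks, elems0), "depth")
})

test_that("tertile categorization is balanced and deterministic", {
  cat9 <- categorize_h3k27me3(1:9)
  expect_equal(which(cat9 == "high"), 7:9)
  expect_equal(which(cat9 == "low"), 1:3)

  ties <- categorize_h3k27me3(rep(1, 9))
  expect_equal(table(ties)[["high"]], 3L)
  expect_equal(which(ties == "high"), 1:3)  # region order breaks ties

  cat4 <- categorize_h3k27me3(c(4, 1, 3, 2))
  tab <- table(cat4)
  expect_lte(abs(tab[["high"]] - tab[["low"]]), 1L)
  expect_error(categorize_h3k27me3(c(1, 2)), "at least 3")
})

test_that("cross-cell-line matrix normalizes rows to their maximum", {
  locks <- gr0("chr1", c(0, 500), c(100, 700))
  t1 <- mk_track(c(0, 500), c(200, 800), c(2, 2))
  single <- cross_cellline_matrix(list(M = list(lineA = t1)), locks)
  expect_true(all(single == 1))
  two <- cross_cellline_matrix(list(M = list(lineA = t1, lineB = t1)), locks)
  expect_true(all(two == 1))
})

test_that("planted bivalent-to-repressive transition is recovered across lines", {
  sc <- shared_cohort()
  truth <- sc$truth
  md <- truth$metadata
  prim <- md$sample_id[md$class == "primitive"][1]
  diff1 <- md$sample_id[md$class == "differentiated"][1]
  cl <- truth$clusters
  biv <- cl[cl$sample_id == prim & cl$bivalent, ]
  locks <- gr0(biv$chrom, biv$start, biv$end)
  tracks <- lapply(c(H3K4me1 = "H3K4me1", H3K27me3 = "H3K27me3",
                     H3K9me3 = "H3K9me3"), function(m) {
    lapply(c(primitive = prim, differentiated = diff1), function(s) {
      read_bedgraph(truth$files$signal[[paste(s, m, sep = "__")]])
    })
  })
  m <- cross_cellline_matrix(tracks, locks)
  expect_equal(unname(which.max(m["H3K4me1", ])), 1L)
  expect_equal(unname(which.max(m["H3K27me3", ])), 1L)
  expect_equal(unname(which.max(m["H3K9me3", ])), 2L)
})
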