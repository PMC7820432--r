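mk_lockset <- function(chrom, start, end, sample_id, mark = "H3K4me1") {
  pk <- gr0(chrom, start, end)
  structure(list(locks = pk, members = as.list(seq_along(pk)),
                 sample_id = sample_id, mark = mark,
                 params_used = NULL, thresholds = numeric(0),
                 relative_sum_trace = data.frame()),
            class = "lock_set")
}

test_that("catalogue merges regions and records presence", {
  a <- mk_lockset("chr1", 0, 100, "A")
  b <- mk_lockset("chr1", 50, 150, "B")
  cat1 <- build_catalogue(list(a, b), "H3K4me1")
  expect_equal(length(cat1$regions), 1L)
  expect_equal(unname(cat1$presence[, 1]), c(1L, 1L))

  d <- mk_lockset("chr1", c(0, 500), c(100, 600), "D")
  e <- mk_lockset("chr1", 0, 100, "E")
  cat2 <- build_catalogue(list(d, e), "H3K4me1")
  expect_equal(length(cat2$regions), 2L)
  expect_equal(unname(cat2$presence["E", ]), c(1L, 0L))

  none <- mk_lockset(character(0), numeric(0), numeric(0), "Z")
  cat3 <- build_catalogue(list(d, none), "H3K4me1")
  expect_true(all(cat3$presence["Z", ] == 0L))

  # a named list of locksets (as produced per cohort) works identically
  cat4 <- build_catalogue(list(D = d, E = e), "H3K4me1")
  expect_equal(cat4$presence, cat2$presence)

  expect_error(build_catalogue(list(a, mk_lockset("chr1", 0, 1, "x", "H3K9me3")),
                               "H3K4me1"), "mark")
})

test_that("catalogue coverage is monotone in samples", {
  set.seed(5)
  sets <- lapply(1:4, function(i) {
    df <- random_peaks(8)
    mk_lockset(df$chrom, df$start, df$end, paste0("s", i))
  })
  cov3 <- genome_coverage(build_catalogue(sets[1:3], "H3K4me1")$regions)
  cov4 <- genome_coverage(build_catalogue(sets, "H3K4me1")$regions)
  expect_gte(cov4, cov3)
})

test_that("tissue assignment uses a strict majority fraction", {
  sets <- list(mk_lockset("chr1", 0, 100, "s1"),
               mk_lockset("chr1", 0, 100, "s2"),
               mk_lockset("chr1", 0, 100, "s3"),
               mk_lockset("chr1", 500, 600, "s4"),
               mk_lockset("chr1", 0, 100, "s5"))
  cat1 <- build_catalogue(sets, "H3K4me1")
  md <- data.frame(sample_id = paste0("s", 1:5),
                   tissue = c("T", "T", "T", "T", "U"))
  # region [0,100): 3 of 4 T samples (0.75 > 0.5) -> assigned
  res <- assign_tissue_locks(cat1, md)
  expect_equal(length(res$T), 1L)
  expect_equal(GenomicRanges::start(res$T), 1L)
  # present in 1 of 1 -> assigned
  expect_equal(length(res$U), 1L)

  # 2 of 4 is not > 0.5 -> not assigned
  sets2 <- list(mk_lockset("chr1", 0, 100, "s1"),
                mk_lockset("chr1", 0, 100, "s2"),
                mk_lockset("chr1", 500, 600, "s3"),
                mk_lockset("chr1", 500, 600, "s4"))
  cat2 <- build_catalogue(sets2, "H3K4me1")
  md2 <- data.frame(sample_id = paste0("s", 1:4), tissue = "T")
  expect_equal(length(assign_tissue_locks(cat2, md2)$T), 0L)
})

test_that("bp Jaccard matches direct arithmetic and is a similarity", {
  a <- gr0("chr1", 0, 100)
  b <- gr0("chr1", 50, 150)
  expect_equal(jaccard(a, a), 1)
  expect_equal(jaccard(a, gr0("chr2", 0, 100)), 0)
  expect_equal(jaccard(a, b), 1 / 3)
  set.seed(9)
  for (i in 1:10) {
    x <- random_peaks(6); y <- random_peaks(6)
    gx <- gr0(x$chrom, x$start, x$end); gy <- gr0(y$chrom, y$start, y$end)
    expect_equal(jaccard(gx, gy), jaccard(gy, gx))
    expect_gte(jaccard(gx, gy), 0); expect_lte(jaccard(gx, gy), 1)
  }
})

test_that("mcc matches the formula, brute force and the correlation identity", {
  expect_equal(mcc(10, 10, 0, 0), 1)
  expect_equal(mcc(1, 1, 1, 1), 0)
  expect_equal(mcc(8, 9, 1, 2), 70 / sqrt(9 * 10 * 10 * 11))
  # MCC equals the Pearson correlation of the binary truth/prediction vectors
  for (tp in 0:5) for (tn in 0:5) for (fp in 0:5) for (fn in 0:5) {
    if (tp + tn + fp + fn == 0) next
    truth <- c(rep(1, tp + fn), rep(0, tn + fp))
    pred <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
    r <- suppressWarnings(stats::cor(truth, pred))
    expect_equal(mcc(tp, tn, fp, fn), if (is.na(r)) 0 else r)
  }
})

test_that("1-NN LOO separates constructed classes and fails forced cases", {
  # two classes with high within-class and low between-class overlap
  sets <- list(mk_lockset("chr1", c(0, 1000), c(500, 1450), "a1"),
               mk_lockset("chr1", c(0, 1000), c(480, 1500), "a2"),
               mk_lockset("chr1", c(5000, 7000), c(5500, 7450), "b1"),
               mk_lockset("chr1", c(5000, 7000), c(5480, 7500), "b2"))
  labels <- c("A", "A", "B", "B")
  rep1 <- nn_classify_loo(sets, labels)
  expect_equal(rep1$predicted, labels)
  expect_equal(rep1$average_mcc, 1)

  # permuted labels over the same similarity structure: mean MCC near 0
  set.seed(21)
  perms <- permute_labels_mcc(rep1, 20)
  expect_lte(abs(mean(perms)), 0.5)

  # two samples, different labels: both must be misclassified
  expect_warning(
    rep2 <- nn_classify_loo(sets[c(1, 3)], c("A", "B")),
    "single sample")
  expect_equal(rep2$average_mcc, -1)

  # presence-vector similarity over the catalogue separates the same classes
  cat1 <- build_catalogue(sets, "H3K4me1")
  pres_rows <- lapply(seq_len(nrow(cat1$presence)),
                      function(i) cat1$presence[i, ])
  rep3 <- nn_classify_loo(pres_rows, labels, method = "presence")
  expect_equal(rep3$predicted, labels)
  expect_equal(rep3$average_mcc, 1)
})
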