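test_that("upper-tail hypergeometric matches closed forms", {
  expect_equal(hypergeom_upper(4, 4, 5, 10), 5 / 210)
  expect_equal(hypergeom_upper(0, 4, 5, 10), 1)
  expect_equal(hypergeom_upper(6, 6, 6, 6), 1)
  expect_error(hypergeom_upper(5, 4, 5, 10), "k <= n")
})

test_that("upper-tail hypergeometric matches enumeration for all N <= 30", {
  for (N in 0:30) {
    tuples <- expand.grid(K = 0:N, n = 0:N)
    got <- c(); want <- c()
    for (r in seq_len(nrow(tuples))) {
      K <- tuples$K[r]; n <- tuples$n[r]
      for (k in 0:min(K, n)) {
        got <- c(got, hypergeom_upper(k, n, K, N))
        want <- c(want, oracle_hyper_upper(k, n, K, N))
      }
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("pathway enrichment uses the custom background", {
  bg <- sprintf("G%03d", 1:100)
  sets <- list(S = sprintf("G%03d", 1:10), other = sprintf("G%03d", 50:69))
  # query = background: no enrichment possible
  res <- pathway_enrichment(bg, bg, sets)
  expect_true(all(res$p_value == 1))
  # a set fully inside a 10-gene query
  res <- pathway_enrichment(sprintf("G%03d", 1:10), bg, sets)
  row <- res[res$set == "S", ]
  expect_equal(row$p_value, 1 / choose(100, 10))
  # set disjoint from background: recorded with K = 0
  res <- pathway_enrichment(sprintf("G%03d", 1:10), bg, list(X = "H999"))
  expect_equal(res$K, 0)
  expect_equal(res$p_value, 1)
  expect_error(pathway_enrichment("G001", character(0), sets), "background")
  expect_warning(pathway_enrichment(c("G001", "H777"), bg, sets), "dropping")
})

test_that("TAD boundary enrichment counts LOCKs within the window", {
  locks <- gr0("chr1", c(0, 50000, 100000, 150000), c(10000, 60000, 110000, 160000))
  categories <- c("high", "high", "low", "low")
  bnd <- gr0("chr1", c(12000, 65000), c(12001, 65001))  # near the two high LOCKs
  res <- tad_boundary_enrichment(locks, categories, bnd)
  expect_equal(res$k[res$category == "high"], 2)
  expect_equal(res$k[res$category == "low"], 0)
  expect_equal(res$p_value[res$category == "high"],
               oracle_hyper_upper(2, 2, 2, 4))
  # boundaries nowhere near any LOCK
  farb <- gr0("chr1", 900000, 900001)
  expect_warning(res <- tad_boundary_enrichment(locks, categories, farb), "no LOCK")
  expect_true(all(res$p_value == 1))
})

test_that("regulator enrichment uses the bp-weighted urn", {
  # category C covers 10% of LOCK bp and holds all sites
  locks <- gr0("chr1", c(0, 20000), c(1000, 29000))  # 1 kb + 9 kb
  categories <- c("high", "low")
  sites <- gr0("chr1", seq(100, 900, by = 100), seq(110, 910, by = 100))
  res <- regulator_enrichment(list(TF = sites), locks, categories)
  hi <- res[res$category == "high", ]
  expect_equal(hi$k, 9)
  expect_equal(hi$n, 1000)
  expect_equal(hi$N, 10000)
  expect_equal(hi$p_value, hypergeom_upper(9, 1000, 9, 10000))
  # query = population: p = 1
  res1 <- regulator_enrichment(list(TF = sites), locks[1], "high")
  expect_equal(res1$p_value, 1)
  # TF with no sites in any LOCK
  far <- gr0("chr1", 500000, 500010)
  expect_warning(res <- regulator_enrichment(list(TF = far), locks, categories),
                 "no sites")
  expect_true(all(res$p_value == 1))
})

test_that("p-values are invariant to relabeling non-query categories", {
  set.seed(47)
  locks <- gr0("chr1", seq(0, by = 20000, length.out = 9),
               seq(0, by = 20000, length.out = 9) + 5000)
  pos <- sort(sample(0:170000, 30))
  sites <- gr0("chr1", pos, pos + 10)
  cats1 <- rep(c("high", "intermediate", "low"), 3)
  cats2 <- rep(c("high", "mid2", "low2"), 3)
  r1 <- regulator_enrichment(list(TF = sites), locks, cats1)
  r2 <- regulator_enrichment(list(TF = sites), locks, cats2)
  expect_equal(r1$p_value[r1$category == "high"],
               r2$p_value[r2$category == "high"])
})

test_that("under uniform site placement the p-value distribution is not anti-conservative", {
  set.seed(53)
  locks <- gr0("chr1", seq(0, by = 10000, length.out = 12),
               seq(0, by = 10000, length.out = 12) + 4000)
  categories <- rep(c("high", "intermediate", "low"), 4)
  n_sim <- 1000
  pvals <- vapply(seq_len(n_sim), function(i) {
    pos <- sample(0:119000, 25)
    sites <- gr0("chr1", sort(pos), sort(pos) + 10)
    res <- regulator_enrichment(list(TF = sites), locks, categories)
    res$p_value[res$category == "high"]
  }, numeric(1))
  grid <- seq(0.05, 0.95, by = 0.05)
  ecdf_vals <- vapply(grid, function(q) mean(pvals <= q), numeric(1))
  expect_true(all(ecdf_vals <= grid + 0.05))
})
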