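# Shared fixtures.  All fixtures are generated in code; the full synthetic
# cohort used by the recovery tests is simulated once per test run and cached.

gr0 <- function(chrom, start, end) granges0(chrom, start, end)

write_tmp <- function(lines, ext = ".bed") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# random disjoint peaks on one chromosome (0-based), for the caller oracle
random_peaks <- function(n, chrom = "chr1") {
  gaps <- sample(c(sample(5:50, n, replace = TRUE),
                   sample(200:2000, n, replace = TRUE)), n)
  widths <- sample(10:100, n, replace = TRUE)
  starts <- cumsum(c(sample(0:100, 1), (widths + gaps)[-n]))
  data.frame(chrom = chrom, start = starts, end = starts + widths)
}

.cohort_cache <- new.env(parent = emptyenv())

# the default-conditions cohort shared by the recovery tests (seed fixed)
shared_cohort <- function() {
  if (!is.null(.cohort_cache$value)) return(.cohort_cache$value)
  dir <- file.path(tempdir(), "lockscape-shared-cohort")
  truth <- simulate_cohort(sim_config(seed = 11L), dir)
  cohort <- load_cohort(dir)
  locks <- call_cohort_locks(cohort)
  .cohort_cache$value <- list(truth = truth, cohort = cohort, locks = locks)
  .cohort_cache$value
}

# the 5-seed replicate runs shared by the recovery and coverage-comparison
# checks: per seed, the per-sample bp-F1 table and the group-comparison table
recovery_runs <- function() {
  if (!is.null(.cohort_cache$recovery)) return(.cohort_cache$recovery)
  runs <- lapply(1:5, function(seed) {
    dir <- file.path(tempdir(), paste0("recovery-cohort-", seed))
    truth <- simulate_cohort(sim_config(seed = seed), dir)
    cohort <- load_cohort(dir)
    locks <- call_cohort_locks(cohort)
    rows <- list()
    for (m in names(locks$locks)) {
      for (sid in names(locks$locks[[m]])) {
        rows[[paste(sid, m)]] <- data.frame(
          seed = seed, sample_id = sid, mark = m,
          f1 = bp_f1(locks$locks[[m]][[sid]]$locks,
                     truth_granges(truth, sid, m))$f1)
      }
    }
    cmp <- compare_groups(cohort_coverage(locks), cohort$metadata)
    cmp$seed <- seed
    unlink(dir, recursive = TRUE)
    list(f1 = do.call(rbind, rows), cmp = cmp)
  })
  .cohort_cache$recovery <- list(
    f1 = do.call(rbind, lapply(runs, `[[`, "f1")),
    cmp = do.call(rbind, lapply(runs, `[[`, "cmp")))
  .cohort_cache$recovery
}

# match called H3K4me1 LOCKs of one primitive sample to the planted bivalency
# flags, returning per-lock logical
planted_bivalent_flags <- function(sc, sample_id) {
  locks_gr <- sc$locks$locks[["H3K4me1"]][[sample_id]]$locks
  tg <- truth_granges(sc$truth, sample_id, "H3K4me1")
  ov <- GenomicRanges::findOverlaps(locks_gr, tg)
  flags <- rep(FALSE, length(locks_gr))
  flags[S4Vectors::queryHits(ov)] <-
    S4Vectors::mcols(tg)$bivalent[S4Vectors::subjectHits(ov)]
  flags
}
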