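# Genomic-coverage summaries and the primitive-vs-differentiated group
# comparison, plus the shared rank tests and Benjamini-Hochberg correction.

#' Genomic coverage of a merged interval set
#' @param regions GRanges (reduced defensively)
#' @return total covered bp
#' @export
genome_coverage <- function(regions) {
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(regions))))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p_values numeric vector of p-values in 0..1
#' @return adjusted values in input order
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must be finite and within [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Two-sided rank test
#'
#' Unpaired: Wilcoxon rank-sum (Mann-Whitney); paired: Wilcoxon signed-rank.
#' Exact p-values for small samples without ties, otherwise the normal
#' approximation with continuity and tie correction.  All-zero differences in
#' paired mode give p = 1 with a degenerate-data flag (attribute
#' `degenerate`).
#'
#' @param x,y numeric vectors (equal length when `paired`)
#' @param paired logical
#' @return the two-sided p-value, with attribute `degenerate`
#' @export
rank_test <- function(x, y, paired = FALSE) {
  if (paired) {
    stopifnot(length(x) == length(y))
    if (all(x == y)) {
      return(structure(1, degenerate = TRUE))
    }
    p <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
  } else {
    p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }
  # fully tied data degenerates the normal approximation (0/0); no evidence
  # against the null either way
  if (!is.finite(p)) {
    return(structure(1, degenerate = TRUE))
  }
  structure(unname(p), degenerate = FALSE)
}

#' Per-sample coverage records for LOCKs and individual elements
#'
#' @param locksets named list (sample id -> `lock_set`)
#' @param peaksets named list (sample id -> GRanges of merged peaks)
#' @param mark mark name attached to the records
#' @return data.frame: sample_id, mark, lock_coverage, element_coverage
#' @export
coverage_records <- function(locksets, peaksets, mark) {
  ids <- names(locksets)
  data.frame(
    sample_id = ids, mark = mark,
    lock_coverage = vapply(locksets, function(l) genome_coverage(l$locks), numeric(1)),
    element_coverage = vapply(peaksets[ids], genome_coverage, numeric(1)),
    row.names = NULL)
}

#' Compare coverage between two sample groups, per mark and feature
#'
#' For each mark x feature (LOCK span coverage and individual-element
#' coverage), computes the fold change as the ratio of group medians and a
#' two-sided rank-sum p-value, then adjusts all p-values computed in the call
#' with Benjamini-Hochberg.
#'
#' @param records data.frame from [coverage_records()] (rows for several
#'   marks may be concatenated)
#' @param metadata data.frame with `sample_id` and `class`
#' @param group_a,group_b class labels; fold change is median(a)/median(b)
#' @return data.frame: mark, feature, n_a, n_b, fold_change, p_value, fdr,
#'   infinite_fold flag
#' @export
compare_groups <- function(records, metadata, group_a = "primitive",
                           group_b = "differentiated") {
  cls <- metadata$class[match(records$sample_id, metadata$sample_id)]
  if (anyNA(cls)) stop("records contain samples missing from metadata")
  out <- list()
  for (m in unique(records$mark)) {
    for (feat in c("LOCK", "individual")) {
      col <- if (feat == "LOCK") "lock_coverage" else "element_coverage"
      a <- records[[col]][records$mark == m & cls == group_a]
      b <- records[[col]][records$mark == m & cls == group_b]
      if (length(a) == 0L || length(b) == 0L) stop("empty group for mark ", m)
      med_b <- median(b)
      fc <- if (med_b == 0) Inf else median(a) / med_b
      p <- as.numeric(rank_test(a, b, paired = FALSE))
      out[[paste(m, feat)]] <- data.frame(
        mark = m, feature = feat, n_a = length(a), n_b = length(b),
        fold_change = fc, p_value = p, infinite_fold = !is.finite(fc))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$fdr <- bh_adjust(res$p_value)
  res
}
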