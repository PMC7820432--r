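# Independent brute-force oracles.  These deliberately share no code with the
# implementation: enumeration and per-base accumulation only.

# exhaustive greedy clustering: enumerate every candidate run of every Order,
# order candidates by (higher Order, chromosome, leftmost), then assign
# greedily.  peaks given as a data.frame chrom/start/end (0-based half-open).
oracle_cluster <- function(peaks, thresholds, o_min) {
  peaks <- peaks[order(peaks$chrom, peaks$start), ]
  cand <- list()
  for (ch in sort(unique(peaks$chrom))) {
    rows <- which(peaks$chrom == ch)
    n <- length(rows)
    for (O in as.integer(names(thresholds))) {
      thr <- thresholds[[as.character(O)]]
      if (O < o_min || !is.finite(thr) || n < O) next
      for (s in seq_len(n - O + 1L)) {
        run <- rows[s:(s + O - 1L)]
        gaps <- peaks$start[run][-1] - peaks$end[run][-O]
        if (max(gaps) <= thr) {
          cand[[length(cand) + 1L]] <- list(order = O, chrom = ch,
                                            first = run[1L], run = run,
                                            max_gap = max(gaps))
        }
      }
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), order = integer(0)))
  }
  pri <- order(-vapply(cand, `[[`, numeric(1), "order"),
               vapply(cand, `[[`, character(1), "chrom"),
               vapply(cand, `[[`, numeric(1), "first"))
  taken <- logical(nrow(peaks))
  out <- list()
  for (cc in cand[pri]) {
    if (any(taken[cc$run])) next
    taken[cc$run] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      chrom = cc$chrom, start = peaks$start[cc$run[1L]],
      end = peaks$end[cc$run[length(cc$run)]], order = cc$order)
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# exact two-sided rank-sum p by enumeration of all group assignments (no ties)
oracle_ranksum <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  splits <- utils::combn(length(pooled), n)
  w_all <- apply(splits, 2L, function(ix) sum(rank(pooled)[ix]))
  pl <- mean(w_all <= w_obs)
  pg <- mean(w_all >= w_obs)
  min(1, 2 * min(pl, pg))
}

# exact two-sided signed-rank p by enumeration of all sign assignments
oracle_signedrank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  pl <- mean(v_all <= v_obs)
  pg <- mean(v_all >= v_obs)
  min(1, 2 * min(pl, pg))
}

# step-up BH by direct formula
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * p[ord][i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# upper-tail hypergeometric by summed binomial coefficients
oracle_hyper_upper <- function(k, n, K, N) {
  if (k == 0) return(1)
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# per-base signal accumulation over 0-based half-open segments
oracle_signal_raw <- function(seg_start, seg_end, seg_value, reg_start, reg_end) {
  L <- max(seg_end, reg_end)
  base_val <- numeric(L)
  for (i in seq_along(seg_start)) {
    base_val[(seg_start[i] + 1):seg_end[i]] <- seg_value[i]
  }
  sum(base_val[(reg_start + 1):reg_end])
}

# all-pairs TSS-to-region distance (0-based; 0 inside, else distance to the
# nearest covered base)
oracle_tss_distance <- function(tss, reg_start, reg_end) {
  vapply(seq_along(reg_start), function(i) {
    if (tss >= reg_start[i] && tss < reg_end[i]) 0
    else min(abs(tss - reg_start[i]), abs(tss - (reg_end[i] - 1)))
  }, numeric(1))
}
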