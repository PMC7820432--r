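# LOCK identification: clusters ("LOCKs") of individual peaks of one histone
# modification, found by grouping runs of consecutive peaks whose internal gaps
# stay below a per-Order stitching-distance threshold, iterating the minimum
# included Order downward until the relative sum (peak bp over LOCK-span bp)
# destabilizes.

#' Parameters for the LOCK caller
#'
#' @param threshold_rule `"knee"` (default) or `"quantile"`; how the stitching
#'   distance for each Order is estimated from that Order's window-size
#'   distribution
#' @param quantile_q quantile used when `threshold_rule = "quantile"`
#' @param min_candidate_windows minimum number of admissible windows an Order
#'   needs to be attested when determining the maximum Order
#' @param near_threshold_epsilon fraction below the threshold within which a
#'   low-Order LOCK's stitching distance counts as "close to" the threshold
#' @param low_order_cutoff Orders at or below this are subject to the
#'   near-threshold filter
#' @param oscillation_limit relative change of the relative sum between
#'   consecutive iterations that counts as a "large oscillation" and stops the
#'   caller (default 5 percent)
#' @param mode_separation an Order is only attested if its stitching
#'   threshold stays within this factor of the order-2 threshold (the knee of
#'   the full gap distribution).  Once candidate runs of an Order can only be
#'   formed by swallowing background-scale gaps, that Order's threshold jumps
#'   to the background scale and the Order is rejected.  Guards against
#'   reading a maximum Order out of a single-mode (all-background) window
#'   distribution, where every window shares the same large max-gap.
#' @return a list of class `caller_params`
#' @export
caller_params <- function(threshold_rule = c("knee", "quantile"),
                          quantile_q = 0.25,
                          min_candidate_windows = 2L,
                          near_threshold_epsilon = 0.1,
                          low_order_cutoff = 3L,
                          oscillation_limit = 0.05,
                          mode_separation = 2) {
  threshold_rule <- match.arg(threshold_rule)
  stopifnot(quantile_q > 0, quantile_q < 1,
            near_threshold_epsilon >= 0, near_threshold_epsilon < 1,
            oscillation_limit > 0, min_candidate_windows >= 1,
            mode_separation >= 1)
  structure(list(threshold_rule = threshold_rule, quantile_q = quantile_q,
                 min_candidate_windows = as.integer(min_candidate_windows),
                 near_threshold_epsilon = near_threshold_epsilon,
                 low_order_cutoff = as.integer(low_order_cutoff),
                 oscillation_limit = oscillation_limit,
                 mode_separation = mode_separation),
            class = "caller_params")
}

.peak_frame <- function(peaks) {
  data.frame(chrom = as.character(seqnames(peaks)),
             start = GenomicRanges::start(peaks),
             end = GenomicRanges::end(peaks),
             stringsAsFactors = FALSE)
}

# rolling max of x over windows of width k (k >= 1)
.rollmax <- function(x, k) {
  if (k == 1L) return(x)
  if (length(x) < k) return(numeric(0))
  do.call(pmax, as.data.frame(embed(x, k)))
}

# gaps between consecutive peaks, half-open convention: next.start - prev.end
# (book-ended peaks have gap 0).  start/end here are 1-based closed.
.chrom_gaps <- function(start, end) {
  n <- length(start)
  if (n < 2L) return(numeric(0))
  start[-1L] - end[-n] - 1
}

.validate_peaks <- function(peaks) {
  if (length(peaks) < 2L) return(invisible(peaks))
  red <- GenomicRanges::reduce(peaks)
  if (length(red) != length(peaks)) {
    stop("peaks must be merged (disjoint, non-book-ended); use read_bed(merge = TRUE)")
  }
  invisible(peaks)
}

#' Window-size distribution for a given Order
#'
#' For every run of `order` consecutive peaks on the same chromosome, the
#' window size is the largest gap between consecutive members of the run.
#'
#' @param peaks sorted, merged `GRanges` of individual elements
#' @param order number of peaks per window (>= 2)
#' @return numeric vector of window sizes in bp, one per run; empty when no
#'   chromosome holds `order` peaks
#' @export
window_size_distribution <- function(peaks, order) {
  if (order < 2L) stop("order must be >= 2")
  pf <- .peak_frame(peaks)
  out <- lapply(split(seq_len(nrow(pf)), pf$chrom), function(ix) {
    if (length(ix) < order) return(numeric(0))
    g <- .chrom_gaps(pf$start[ix], pf$end[ix])
    .rollmax(g, order - 1L)
  })
  as.numeric(unlist(out[order(names(out))], use.names = FALSE))
}

#' Stitching-distance threshold for one Order
#'
#' The default knee rule sorts the window sizes ascending, log10-transforms
#' them (`log10(x + 1)`), and returns the value at the point with the largest
#' perpendicular distance below the chord joining the first and last points
#' (ties resolved toward the smaller index).  With a bimodal gap structure
#' (tight intra-cluster gaps vs large background gaps) this lands on the
#' largest intra-cluster window.  The quantile rule returns the empirical
#' inverse-ECDF (type 1) quantile, which is always an attained window size.
#'
#' @param window_sizes numeric vector from [window_size_distribution()]
#' @param rule `"knee"` or `"quantile"`
#' @param q quantile for the quantile rule
#' @return threshold in bp; window sizes `<= threshold` are admissible.
#'   `NA_real_` for an empty input (the Order is unusable).
#' @export
stitching_threshold <- function(window_sizes, rule = c("knee", "quantile"), q = 0.25) {
  rule <- match.arg(rule)
  if (length(window_sizes) == 0L) return(NA_real_)
  if (rule == "quantile") {
    return(unname(quantile(window_sizes, probs = q, type = 1)))
  }
  s <- sort(window_sizes)
  n <- length(s)
  if (n == 1L) return(s)
  y <- log10(s + 1)
  dx <- n - 1
  dy <- y[n] - y[1L]
  # distance below the chord (elbow of a convex ascending curve); points above
  # the chord are clamped to 0
  d <- pmax(0, dy * (seq_len(n) - 1) - dx * (y - y[1L]))
  s[which.max(d)]
}

# thresholds for Orders 2..o_max as a named numeric vector; NA marks an Order
# whose window-size distribution exists but yields no usable threshold (none
# at all, or one off the scale of the order-2 threshold: with a heavy-tailed
# background-gap distribution the knee chord can land inside the background
# mode for Orders where tight windows are rare)
.compute_thresholds <- function(peaks, params, o_max) {
  orders <- seq.int(2L, o_max)
  raw <- vapply(orders, function(O) {
    ws <- window_size_distribution(peaks, O)
    if (length(ws) == 0L) return(NA_real_)
    stitching_threshold(ws, rule = params$threshold_rule, q = params$quantile_q)
  }, numeric(1)) |> stats::setNames(as.character(orders))
  thr2 <- raw[["2"]]
  if (is.finite(thr2)) {
    raw[is.finite(raw) &
          raw > params$mode_separation * max(thr2, .Machine$double.eps)] <- NA_real_
  }
  raw
}

.order_attested <- function(ws, thr, thr2, params) {
  if (length(ws) == 0L || !is.finite(thr)) return(FALSE)
  if (sum(ws <= thr) < params$min_candidate_windows) return(FALSE)
  thr <= params$mode_separation * max(thr2, .Machine$double.eps)
}

#' Maximum Order of clusters attested by the peak set
#'
#' The largest Order O for which at least `min_candidate_windows` windows of
#' O consecutive peaks fall at or below the stitching threshold of that
#' Order, with the Order's threshold remaining on the scale of the order-2
#' threshold (see `mode_separation` in [caller_params()]).  Returns 1
#' (meaning "no LOCKs") when no Order qualifies.
#'
#' @param peaks sorted, merged `GRanges`
#' @param params a [caller_params()] object
#' @return integer Order
#' @export
max_order <- function(peaks, params = caller_params()) {
  pf <- .peak_frame(peaks)
  longest_run <- if (nrow(pf) == 0L) 0L else max(table(pf$chrom))
  if (longest_run < 2L) return(1L)
  thr2 <- stitching_threshold(window_size_distribution(peaks, 2L),
                              rule = params$threshold_rule, q = params$quantile_q)
  if (!is.finite(thr2)) return(1L)
  best <- 1L
  for (O in seq.int(2L, longest_run)) {
    ws <- window_size_distribution(peaks, O)
    if (length(ws) == 0L) break
    # every (O+1)-window contains an O-window, so window minima are
    # non-decreasing in O: once no window sits at the admissible scale,
    # no higher Order can be attested
    if (min(ws) > params$mode_separation * thr2) break
    thr <- stitching_threshold(ws, rule = params$threshold_rule, q = params$quantile_q)
    if (.order_attested(ws, thr, thr2, params)) best <- O
  }
  best
}

.new_lock_set <- function(recs, sample_id, mark, params, thresholds, trace) {
  if (length(recs) == 0L) {
    gr <- GenomicRanges::GRanges()
    members <- list()
  } else {
    chrom <- vapply(recs, `[[`, character(1), "chrom")
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
      start = vapply(recs, `[[`, numeric(1), "start"),
      end = vapply(recs, `[[`, numeric(1), "end")))
    mcols(gr)$order <- vapply(recs, `[[`, numeric(1), "order")
    mcols(gr)$max_gap <- vapply(recs, `[[`, numeric(1), "max_gap")
    members <- lapply(recs, `[[`, "members")
    seqlevels(gr) <- sort(seqlevels(gr))
    ord <- order(as.character(seqnames(gr)), GenomicRanges::start(gr))
    gr <- gr[ord]
    members <- members[ord]
  }
  structure(list(locks = gr, members = members, sample_id = sample_id,
                 mark = mark, params_used = params, thresholds = thresholds,
                 relative_sum_trace = trace),
            class = "lock_set")
}

#' @export
print.lock_set <- function(x, ...) {
  cat("lock_set:", length(x$locks), "LOCKs",
      if (!is.null(x$sample_id)) paste0("(", x$sample_id, ", ", x$mark, ")"),
      "\n")
  if (length(x$locks)) {
    cat("  span:", format(sum(GenomicRanges::width(x$locks)), big.mark = ","),
        "bp; Orders", min(mcols(x$locks)$order), "-", max(mcols(x$locks)$order), "\n")
  }
  if (nrow(x$relative_sum_trace)) {
    cat("  iterations:", nrow(x$relative_sum_trace), "; final relative sum:",
        signif(utils::tail(x$relative_sum_trace$relative_sum, 1), 4), "\n")
  }
  invisible(x)
}

# precomputed clustering context: per-chromosome peak indices, and for every
# Order the admissible run starts and window values under the thresholds
.cluster_context <- function(pf, thresholds) {
  idx_by_chrom <- split(seq_len(nrow(pf)), pf$chrom)
  idx_by_chrom <- idx_by_chrom[order(names(idx_by_chrom))]
  orders <- sort(as.integer(names(thresholds)), decreasing = TRUE)
  cand <- list()
  for (ch in names(idx_by_chrom)) {
    ix <- idx_by_chrom[[ch]]
    g <- .chrom_gaps(pf$start[ix], pf$end[ix])
    for (O in orders) {
      thr <- thresholds[[as.character(O)]]
      if (!is.finite(thr) || length(ix) < O) next
      wv <- .rollmax(g, O - 1L)
      s <- which(wv <= thr)
      if (length(s)) {
        cand[[paste(O, ch)]] <- list(order = O, first = ix[s], wv = wv[s])
      }
    }
  }
  # priority: higher Order first, then chromosome, then leftmost
  ord <- order(-vapply(cand, `[[`, numeric(1), "order"))
  list(pf = pf, cand = cand[ord], orders = orders)
}

# greedy assignment for one o_min; returns plain-record list
.greedy_recs <- function(ctx, o_min) {
  pf <- ctx$pf
  assigned <- logical(nrow(pf))
  recs <- list()
  for (cc in ctx$cand) {
    O <- cc$order
    if (O < o_min) next
    for (j in seq_along(cc$first)) {
      run <- cc$first[j]:(cc$first[j] + O - 1L)
      if (any(assigned[run])) next
      assigned[run] <- TRUE
      recs[[length(recs) + 1L]] <- list(
        chrom = pf$chrom[run[1L]], start = pf$start[run[1L]],
        end = pf$end[run[O]], order = O, max_gap = cc$wv[j], members = run)
    }
  }
  recs
}

.filter_recs <- function(recs, thresholds, params) {
  keep <- vapply(recs, function(r) {
    thr <- thresholds[[as.character(r$order)]]
    !(r$order <= params$low_order_cutoff && is.finite(thr) &&
        r$max_gap > (1 - params$near_threshold_epsilon) * thr)
  }, logical(1))
  recs[keep]
}

# relative sum from plain records: member-peak bp over span bp (members are
# exactly the peaks inside each span, since runs are consecutive)
.recs_relative_sum <- function(recs, peak_width) {
  span <- sum(vapply(recs, function(r) r$end - r$start + 1, numeric(1)))
  if (span == 0) return(NA_real_)
  covered <- sum(vapply(recs, function(r) sum(peak_width[r$members]), numeric(1)))
  covered / span
}

#' Cluster peaks into LOCKs, highest Order first
#'
#' Scans each chromosome left to right, once per Order from the highest down
#' to `o_min`: any run of O consecutive unassigned peaks whose largest internal
#' gap is at or below `thresholds[[as.character(O)]]` becomes a LOCK and its
#' peaks are marked assigned.  Conflicts therefore resolve to the higher
#' Order, then to the leftmost run.
#'
#' @param peaks sorted, merged `GRanges`
#' @param thresholds named numeric vector of stitching thresholds, names =
#'   Orders; `NA` entries are skipped
#' @param o_min smallest Order to cluster (>= 2)
#' @param sample_id,mark,params optional annotations carried into the result
#' @return a `lock_set`
#' @export
cluster_peaks <- function(peaks, thresholds, o_min, sample_id = NULL,
                          mark = NULL, params = NULL) {
  if (o_min < 2L) stop("o_min must be >= 2")
  ctx <- .cluster_context(.peak_frame(peaks), thresholds)
  recs <- .greedy_recs(ctx, o_min)
  .new_lock_set(recs, sample_id, mark, params, thresholds,
                data.frame(iteration = integer(0), o_min = integer(0),
                           n_locks = integer(0), relative_sum = numeric(0)))
}

#' Filter low-Order LOCKs whose stitching distance sits near the threshold
#'
#' Removes LOCKs with Order at or below `low_order_cutoff` whose largest
#' internal gap exceeds `(1 - near_threshold_epsilon)` times the stitching
#' threshold of their Order.  Released peaks are not re-clustered within the
#' same iteration.
#'
#' @param locks a `lock_set` with thresholds recorded
#' @param params a [caller_params()] object
#' @return the filtered `lock_set`
#' @export
filter_near_threshold <- function(locks, params = caller_params()) {
  stopifnot(inherits(locks, "lock_set"))
  gr <- locks$locks
  if (length(gr) == 0L) return(locks)
  thr <- locks$thresholds[as.character(mcols(gr)$order)]
  drop <- mcols(gr)$order <= params$low_order_cutoff &
    is.finite(thr) &
    mcols(gr)$max_gap > (1 - params$near_threshold_epsilon) * thr
  locks$locks <- gr[!drop]
  locks$members <- locks$members[!drop]
  locks
}

#' Relative sum of a LOCK set
#'
#' The fraction of the LOCK-spanned base pairs that is covered by the
#' individual elements: sum of peak bp inside LOCK spans over sum of LOCK span
#' bp.  This is the caller's stopping statistic.
#'
#' @param locks a `lock_set`
#' @param peaks the `GRanges` the LOCKs were called from
#' @return a fraction in (0, 1], or `NA_real_` when the LOCK set is empty
#'   (the undefined signal)
#' @export
relative_sum <- function(locks, peaks) {
  stopifnot(inherits(locks, "lock_set"))
  spans <- GenomicRanges::reduce(locks$locks)
  denom <- sum(as.numeric(GenomicRanges::width(spans)))
  if (denom == 0) return(NA_real_)
  num <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::intersect(spans, GenomicRanges::reduce(peaks)))))
  num / denom
}

#' Call LOCKs from a merged peak set
#'
#' Runs the full identification procedure: per-Order window-size
#' distributions, stitching thresholds, maximum Order, highest-Order-first
#' clustering, and the near-threshold filter, iterated with the minimum
#' included Order lowered from the maximum Order toward 2.  After each
#' iteration the relative sum is computed; the caller stops when the relative
#' sum starts oscillating, i.e. when its difference to the previous iteration
#' reverses direction with a relative magnitude above `oscillation_limit`,
#' and returns the LOCK set of the iteration before the reversal (the last
#' stable one).  A monotone drift of the relative sum, as produced by steadily
#' admitting lower Orders, does not stop the caller.  If no oscillation
#' occurs, the result of the final (`o_min = 2`) iteration is returned.  The
#' full trace is recorded in `$relative_sum_trace`.
#'
#' @param peaks sorted, merged `GRanges` of individual elements
#' @param params a [caller_params()] object
#' @param sample_id,mark optional annotations
#' @return a `lock_set`
#' @export
call_locks <- function(peaks, params = caller_params(),
                       sample_id = NULL, mark = NULL) {
  peaks <- sort_intervals(peaks)
  .validate_peaks(peaks)
  empty_trace <- data.frame(iteration = integer(0), o_min = integer(0),
                            n_locks = integer(0), relative_sum = numeric(0))
  if (length(peaks) < 2L) {
    return(.new_lock_set(list(), sample_id, mark, params, numeric(0), empty_trace))
  }
  o_max <- max_order(peaks, params)
  if (o_max < 2L) {
    return(.new_lock_set(list(), sample_id, mark, params, numeric(0), empty_trace))
  }
  thresholds <- .compute_thresholds(peaks, params, o_max)
  pf <- .peak_frame(peaks)
  ctx <- .cluster_context(pf, thresholds)
  peak_width <- pf$end - pf$start + 1
  trace <- empty_trace
  prev <- NULL
  rs_hist <- numeric(0)
  it <- 0L
  for (o_min in seq.int(o_max, 2L)) {
    it <- it + 1L
    recs <- .filter_recs(.greedy_recs(ctx, o_min), thresholds, params)
    rs <- .recs_relative_sum(recs, peak_width)
    trace <- rbind(trace, data.frame(iteration = it, o_min = o_min,
                                     n_locks = length(recs),
                                     relative_sum = rs))
    h <- length(rs_hist)
    if (h >= 2L && is.finite(rs) && all(is.finite(rs_hist[h - 1:0]))) {
      d_now <- rs - rs_hist[h]
      d_prev <- rs_hist[h] - rs_hist[h - 1L]
      if (d_now * d_prev < 0 &&
          abs(d_now) / rs_hist[h] > params$oscillation_limit) {
        return(.new_lock_set(prev, sample_id, mark, params, thresholds, trace))
      }
    }
    prev <- recs
    rs_hist <- c(rs_hist, rs)
  }
  .new_lock_set(prev, sample_id, mark, params, thresholds, trace)
}
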