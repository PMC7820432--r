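# Repressive-signal quantification over active LOCKs: signal integrals,
# normalization against individual elements, high/intermediate/low
# categorization, and the cross-cell-line signal matrix.

#' Signal overlap of a track with regions
#'
#' For each region, `raw` is the integral of the track over the region
#' (sum over intersecting segments of value x overlapped bp, signal x bp) and
#' `per_bp` is `raw` divided by the region length.
#'
#' @param track a `signal_track`
#' @param regions GRanges, optionally with a `region_id` metadata column
#' @return data.frame: region_id, width, raw, per_bp
#' @export
signal_over_intervals <- function(track, regions) {
  stopifnot(inherits(track, "signal_track"))
  ids <- mcols(regions)$region_id %||% paste0("region_", seq_along(regions))
  raw <- numeric(length(regions))
  if (length(regions) > 0L && length(track$segments) > 0L) {
    missing_chrom <- setdiff(unique(as.character(seqnames(regions))),
                             unique(as.character(seqnames(track$segments))))
    if (length(missing_chrom)) {
      warning("region chromosome(s) absent from track: ",
              paste(missing_chrom, collapse = ", "), "; raw = 0 there")
    }
    # regions on chromosomes the track lacks are handled above; silence the
    # seqlevel-merge notice findOverlaps emits for them
    hits <- suppressWarnings(GenomicRanges::findOverlaps(regions, track$segments))
    if (length(hits) > 0L) {
      ov_w <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(regions)[queryHits(hits)],
        GenomicRanges::ranges(track$segments)[subjectHits(hits)]))
      contrib <- as.numeric(ov_w) * mcols(track$segments)$value[subjectHits(hits)]
      agg <- tapply(contrib, queryHits(hits), sum)
      raw[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  w <- as.numeric(GenomicRanges::width(regions))
  data.frame(region_id = ids, width = w, raw = raw, per_bp = raw / w)
}

#' Normalize LOCK signal to the individual elements of the same profile
#'
#' Divides each LOCK's per-bp signal by the median per-bp signal over the
#' individual elements of the same profile, making the score invariant to
#' global rescaling of the track.
#'
#' @param lock_overlaps data.frame from [signal_over_intervals()] over LOCKs
#' @param element_overlaps data.frame from [signal_over_intervals()] over the
#'   individual elements
#' @return `lock_overlaps` with a `normalized` column
#' @export
normalize_to_individual <- function(lock_overlaps, element_overlaps) {
  if (nrow(element_overlaps) == 0L) stop("element overlaps are empty")
  med <- median(element_overlaps$per_bp)
  if (!is.finite(med) || med <= 0) {
    stop("median element signal is not positive; check the track depth")
  }
  lock_overlaps$normalized <- lock_overlaps$per_bp / med
  lock_overlaps
}

# balanced split of n into (high, intermediate, low); high and low sizes
# differ by at most 1 from each other and from n/3
.tertile_sizes <- function(n) {
  base <- n %/% 3L
  extra <- n %% 3L
  n_high <- base + as.integer(extra == 2L)
  n_low <- n_high
  c(high = n_high, intermediate = n - n_high - n_low, low = n_low)
}

#' Categorize regions by normalized repressive-signal level
#'
#' Tertile split: the top third of normalized values is `high`, the bottom
#' third `low`, the rest `intermediate`.  Ties are broken by region order so
#' the split is deterministic.
#'
#' @param normalized numeric vector of normalized signal values
#' @return character vector of categories, same order as the input
#' @export
categorize_h3k27me3 <- function(normalized) {
  n <- length(normalized)
  if (n < 3L) stop("need at least 3 regions to form categories")
  sizes <- .tertile_sizes(n)
  ord <- order(-normalized, seq_len(n))
  category <- rep("intermediate", n)
  category[ord[seq_len(sizes[["high"]])]] <- "high"
  category[ord[seq.int(n - sizes[["low"]] + 1L, n)]] <- "low"
  category
}

#' Cross-cell-line signal matrix over a fixed LOCK set
#'
#' For each (mark, cell line) track the entry is the median over LOCKs of
#' raw signal / track depth / LOCK length; each mark's row is then divided by
#' its maximum across cell lines, so every row has maximum 1.
#'
#' @param tracks nested named list: `tracks[[mark]][[cell_line]]` is a
#'   `signal_track`
#' @param locks GRanges: the LOCK set evaluated for every track
#' @return numeric matrix, rows = marks, columns = cell lines, values in (0, 1]
#' @export
cross_cellline_matrix <- function(tracks, locks) {
  marks <- names(tracks)
  lines <- names(tracks[[1L]])
  m <- matrix(NA_real_, length(marks), length(lines),
              dimnames = list(marks, lines))
  for (mk in marks) {
    for (ln in lines) {
      tr <- tracks[[mk]][[ln]]
      if (tr$depth <= 0) stop("track (", mk, ", ", ln, ") has zero depth")
      ov <- signal_over_intervals(tr, locks)
      m[mk, ln] <- median(ov$raw / tr$depth / ov$width)
    }
  }
  sweep(m, 1L, apply(m, 1L, max), "/")
}
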