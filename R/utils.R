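# Small shared helpers.

#' Base-pair precision/recall/F1 between two interval sets
#'
#' @param called GRanges (e.g. called LOCK spans)
#' @param truth GRanges (e.g. planted cluster spans)
#' @return list: precision, recall, f1 (all bp-level)
#' @export
bp_f1 <- function(called, truth) {
  called <- GenomicRanges::reduce(called)
  truth <- GenomicRanges::reduce(truth)
  inter <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::intersect(called, truth))))
  cbp <- sum(as.numeric(GenomicRanges::width(called)))
  tbp <- sum(as.numeric(GenomicRanges::width(truth)))
  precision <- if (cbp == 0) 0 else inter / cbp
  recall <- if (tbp == 0) 0 else inter / tbp
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Build a GRanges from 0-based half-open coordinates
#'
#' Convenience for constructing interval sets in the BED convention used by
#' all on-disk formats.
#'
#' @param chrom chromosome names
#' @param start 0-based starts
#' @param end half-open ends
#' @return sorted GRanges
#' @export
granges0 <- function(chrom, start, end) {
  .bed_to_granges(chrom, start, end)
}
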