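# TSS-anchored association of genes with regions and expression comparison.

# distance between a TSS (0-based position t) and a 0-based half-open region
# [s, e): 0 when inside, else min(|t - s|, |t - (e - 1)|), i.e. distance to
# the nearest covered base.  In 1-based closed GRanges coordinates [S, E]
# with TSS base T this is max(S - T, T - E, 0).
.tss_distance <- function(tss_base, region_start, region_end) {
  pmax(region_start - tss_base, tss_base - region_end, 0)
}

#' Associate genes with regions by TSS distance
#'
#' A gene associates with a region when the distance from its TSS to the
#' region (0 if the TSS falls inside) is at most `window` bp ("within 10 kb",
#' inclusive).  Strand is ignored; a gene may associate with several regions.
#'
#' @param regions merged GRanges, optionally named via a `region_id` metadata
#'   column (defaults to `region_<i>`)
#' @param genes data.frame with columns gene_id, chrom, tss (0-based), strand
#'   (as from [read_tss_bed()])
#' @param window association window in bp (default 10000)
#' @return data.frame: gene_id, region_id, distance
#' @export
associate_genes <- function(regions, genes, window = 10000) {
  if (is.null(mcols(regions)$region_id)) {
    mcols(regions)$region_id <- paste0("region_", seq_along(regions))
  }
  if (length(regions) == 0L || nrow(genes) == 0L) {
    return(data.frame(gene_id = character(0), region_id = character(0),
                      distance = numeric(0)))
  }
  tss_gr <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(start = genes$tss + 1, width = 1))
  hits <- GenomicRanges::findOverlaps(tss_gr, regions, maxgap = window,
                                      ignore.strand = TRUE)
  qi <- queryHits(hits)
  si <- subjectHits(hits)
  d <- .tss_distance(genes$tss[qi] + 1,
                     GenomicRanges::start(regions)[si],
                     GenomicRanges::end(regions)[si])
  keep <- d <= window
  out <- data.frame(gene_id = genes$gene_id[qi][keep],
                    region_id = mcols(regions)$region_id[si][keep],
                    distance = d[keep])
  out[order(match(out$gene_id, genes$gene_id), out$distance), , drop = FALSE]
}

#' Compare expression between two gene sets
#'
#' Two-sided rank-sum test on the expression values of two deduplicated gene
#' sets in one cell type / sample column.
#'
#' @param genes_a,genes_b character vectors of gene ids
#' @param expression data.frame from [read_expression()] (rownames = gene_id)
#' @param cell_type column of `expression` to use
#' @return list: p_value, median_a, median_b, n_a, n_b, direction
#'   (`"a>b"`, `"a<b"` or `"a=b"`)
#' @export
compare_expression <- function(genes_a, genes_b, expression, cell_type) {
  if (!cell_type %in% names(expression)) {
    stop("cell type '", cell_type, "' not found in expression table")
  }
  a <- unique(genes_a)[unique(genes_a) %in% rownames(expression)]
  b <- unique(genes_b)[unique(genes_b) %in% rownames(expression)]
  if (length(a) == 0L) stop("no genes of set A found in the expression table")
  if (length(b) == 0L) stop("no genes of set B found in the expression table")
  va <- expression[a, cell_type]
  vb <- expression[b, cell_type]
  p <- rank_test(va, vb, paired = FALSE)
  list(p_value = as.numeric(p), median_a = median(va), median_b = median(vb),
       n_a = length(a), n_b = length(b),
       direction = if (median(va) > median(vb)) "a>b"
                   else if (median(va) < median(vb)) "a<b" else "a=b")
}
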