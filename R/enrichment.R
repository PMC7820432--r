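# Hypergeometric over-representation tests with the custom backgrounds used
# throughout the downstream analyses: pathways against an
# individual-element-derived gene background, LOCK signal categories at TAD
# boundaries, and regulator binding in bivalent LOCKs (a bp-weighted urn).

#' Upper-tail hypergeometric p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing `n` items from a
#' population of `N` containing `K` successes.  Computed in log space.
#'
#' @param k successes observed in the query
#' @param n query size
#' @param K successes in the population
#' @param N population size
#' @return p-value in (0, 1]
#' @export
hypergeom_upper <- function(k, n, K, N) {
  stopifnot(k >= 0, n >= 0, K >= 0, N >= 0, k <= n, k <= K, n <= N, K <= N)
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Gene-set over-representation with a custom background
#'
#' For each set S: population N = background genes, K = background genes in
#' S, query n = query genes, k = query genes in S; upper-tail hypergeometric
#' p, BH-adjusted across all sets tested.  Query genes outside the background
#' are dropped with a warning.
#'
#' @param query_genes character vector (e.g. LOCK-associated genes)
#' @param background_genes character vector (e.g. genes associated with all
#'   individual elements)
#' @param gene_sets named list of character vectors, as from [read_gmt()]
#' @return data.frame: set, k, n, K, N, p_value, fdr
#' @export
pathway_enrichment <- function(query_genes, background_genes, gene_sets) {
  background <- unique(background_genes)
  if (length(background) == 0L) stop("background gene list is empty")
  query <- unique(query_genes)
  dropped <- setdiff(query, background)
  if (length(dropped)) {
    warning("dropping ", length(dropped),
            " query gene(s) outside the background: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
    query <- intersect(query, background)
  }
  n <- length(query)
  N <- length(background)
  res <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    K <- length(intersect(gene_sets[[nm]], background))
    k <- length(intersect(gene_sets[[nm]], query))
    data.frame(set = nm, k = k, n = n, K = K, N = N,
               p_value = hypergeom_upper(k, n, K, N))
  }))
  res$fdr <- bh_adjust(res$p_value)
  res
}

# edge-to-edge distance (inclusive-bp convention shared with gene
# association) between each region and its nearest boundary
.min_boundary_distance <- function(regions, boundaries) {
  d <- rep(Inf, length(regions))
  if (length(boundaries) == 0L) return(d)
  nearest <- GenomicRanges::distanceToNearest(regions, boundaries,
                                              ignore.strand = TRUE)
  # GRanges distance counts strictly-between bases: adjacent = 0; convert to
  # the package-wide convention (nearest-covered-base distance; overlap = 0)
  gapped <- mcols(nearest)$distance
  d[queryHits(nearest)] <- ifelse(gapped > 0, gapped + 1, 0)
  d
}

#' Enrichment of LOCK signal categories at TAD boundaries
#'
#' A LOCK is "at a boundary" when its edge-to-edge distance to the nearest
#' boundary is at most `window` bp.  For each category C the urn is:
#' population N = all LOCKs, successes K = LOCKs at boundaries, query n =
#' LOCKs in C, observed k = LOCKs in C at boundaries; upper-tail
#' hypergeometric p, BH across categories.
#'
#' @param locks GRanges of LOCKs
#' @param categories character vector (e.g. from [categorize_h3k27me3()]),
#'   one per LOCK
#' @param boundaries GRanges of TAD boundaries
#' @param window distance window in bp (default 10000)
#' @return data.frame: category, k, n, K, N, p_value, fdr, at_boundary flag
#'   summary
#' @export
tad_boundary_enrichment <- function(locks, categories, boundaries, window = 10000) {
  stopifnot(length(locks) == length(categories), length(boundaries) >= 1L)
  at_bnd <- .min_boundary_distance(locks, boundaries) <= window
  if (!any(at_bnd)) warning("no LOCK lies within ", window, " bp of a boundary")
  N <- length(locks)
  K <- sum(at_bnd)
  res <- do.call(rbind, lapply(sort(unique(categories)), function(cat) {
    in_cat <- categories == cat
    data.frame(category = cat, k = sum(in_cat & at_bnd), n = sum(in_cat),
               K = K, N = N,
               p_value = hypergeom_upper(sum(in_cat & at_bnd), sum(in_cat), K, N))
  }))
  res$fdr <- bh_adjust(res$p_value)
  res
}

#' Regulator binding-site enrichment in LOCK categories (bp-weighted urn)
#'
#' Realizes "binding counts normalized to LOCK size" as a base-pair-
#' proportional null: population N = total bp of all LOCKs, successes K =
#' total TF sites falling in LOCKs, query n = bp of the category's LOCKs,
#' observed k = TF sites in the category's LOCKs.  Upper-tail hypergeometric
#' p per TF x category, BH across all tests.  A site is counted in the LOCK
#' containing its start position.
#'
#' @param binding_sites named list: TF name -> GRanges of binding sites
#' @param locks GRanges of LOCKs
#' @param categories character vector, one per LOCK
#' @return data.frame: tf, category, k, n, K, N, p_value, fdr
#' @export
regulator_enrichment <- function(binding_sites, locks, categories) {
  stopifnot(length(locks) == length(categories))
  N <- sum(as.numeric(GenomicRanges::width(locks)))
  res <- list()
  for (tf in names(binding_sites)) {
    anchors <- GenomicRanges::resize(binding_sites[[tf]], width = 1L, fix = "start")
    ov <- GenomicRanges::countOverlaps(locks, anchors)
    K <- sum(ov)
    if (K == 0L) {
      warning("TF '", tf, "' has no sites in any LOCK; p = 1")
    }
    for (cat in sort(unique(categories))) {
      in_cat <- categories == cat
      n_bp <- sum(as.numeric(GenomicRanges::width(locks[in_cat])))
      k <- sum(ov[in_cat])
      res[[paste(tf, cat)]] <- data.frame(
        tf = tf, category = cat, k = k, n = n_bp, K = K, N = N,
        p_value = if (K == 0L) 1 else hypergeom_upper(k, n_bp, K, N))
    }
  }
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res$fdr <- bh_adjust(res$p_value)
  res
}
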