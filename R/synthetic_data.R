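# Synthetic cohort generator with planted ground truth.
#
# The generator emulates the structures the downstream analyses look for:
# bimodal inter-peak gap structure (tight intra-cluster gaps vs wide
# background gaps), class-dependent active-mark clustered coverage
# (primitive >> differentiated), bivalent clusters (elevated H3K27me3 signal
# over a subset of primitive H3K4me1 clusters) preferentially placed near
# planted TAD boundaries, TF binding sites concentrated inside bivalent
# clusters, and expression suppression of genes whose TSS lies near a
# bivalent cluster.  Cluster positions come from a fixed per-mark "slot" grid
# so that samples of the same tissue (which draw from a shared slot pool)
# share domain locations, giving the classifier a signal to recover.

#' Configuration for the synthetic cohort generator
#'
#' Defaults define the study conditions used throughout the package's tests
#' and analyses; see the methods vignette for the reasoning behind each value.
#'
#' @param n_chromosomes number of chromosomes
#' @param chrom_length chromosome length, bp
#' @param n_samples_per_class named list: samples per class
#' @param tissues named list: tissue labels per class (samples are split
#'   evenly across tissues)
#' @param marks named character vector: mark name -> "active" or "repressive"
#' @param n_clusters_per_sample planted clusters per primitive sample for
#'   active marks; differentiated samples get `round(n / coverage_fold_primitive)`
#' @param n_repressive_clusters planted clusters per sample for repressive
#'   marks (same in both classes: planted fold 1)
#' @param cluster_order_range integer range (min, max) of peaks per cluster
#' @param intra_cluster_gap list(mean, sd, min, max): bp gap between peaks
#'   within a cluster (clamped normal)
#' @param background_gap list(mean, sd, min, max): bp gap outside clusters
#' @param peak_length list(mean, sd, min, max): bp length of each peak
#' @param singletons_per_chrom unclustered background peaks per chromosome
#' @param coverage_fold_primitive target ratio of primitive to differentiated
#'   active-mark clustered coverage
#' @param bivalent_fraction fraction of the primitive H3K4me1 slot pool given
#'   elevated H3K27me3 signal
#' @param boundary_bias probability that a bivalent slot receives a TAD
#'   boundary within 10 kb
#' @param n_background_boundaries TAD boundaries planted far from any cluster
#' @param tf_sites_per_bivalent_lock binding sites per bivalent slot for the
#'   enriched TFs (CTCF, RAD21, ZNF143)
#' @param n_background_tf_sites genome-wide background sites per enriched TF
#' @param n_uniform_tf_sites genome-wide sites for the uniform TF (YY1)
#' @param expression_suppression multiplicative factor applied to a gene's
#'   expression in samples where its TSS lies within 10 kb of a bivalent
#'   cluster
#' @param genes_per_slot genes planted near each H3K4me1 slot
#' @param n_background_genes genes planted far from slots
#' @param background_signal bedGraph background level, signal per bp
#' @param bivalent_signal_fold fold elevation of planted signal over background
#' @param signal_bin bedGraph bin width, bp
#' @param slots_per_chrom cluster slots per chromosome per mark
#' @param seed integer seed; all randomness derives from it
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_length = 3e6,
                       n_samples_per_class = list(primitive = 8L, differentiated = 8L),
                       tissues = list(primitive = c("ESC", "iPSC"),
                                      differentiated = c("blood", "brain")),
                       marks = c(H3K4me1 = "active", H3K27ac = "active",
                                 H3K27me3 = "repressive", H3K9me3 = "repressive"),
                       n_clusters_per_sample = 30L,
                       n_repressive_clusters = 20L,
                       cluster_order_range = c(8L, 25L),
                       intra_cluster_gap = list(mean = 1200, sd = 400, min = 1, max = 2000),
                       background_gap = list(mean = 60000, sd = 15000, min = 20000, max = 120000),
                       peak_length = list(mean = 800, sd = 150, min = 300, max = 1200),
                       singletons_per_chrom = 15L,
                       coverage_fold_primitive = 3,
                       bivalent_fraction = 0.3,
                       boundary_bias = 0.9,
                       n_background_boundaries = 10L,
                       tf_sites_per_bivalent_lock = 5L,
                       n_background_tf_sites = 30L,
                       n_uniform_tf_sites = 60L,
                       expression_suppression = 0.2,
                       genes_per_slot = 3L,
                       n_background_genes = 100L,
                       background_signal = 1.0,
                       bivalent_signal_fold = 3.5,
                       signal_bin = 2000L,
                       slots_per_chrom = 25L,
                       seed = 1L) {
  marks <- unlist(marks)  # accept the named-list form (natural in YAML)
  cfg <- as.list(environment())
  cfg$marks <- marks
  if (!"H3K4me1" %in% names(marks) || marks[["H3K4me1"]] != "active") {
    stop("marks must include H3K4me1 as an active mark: the bivalency, TAD,",
         " TF and gene structures are anchored on the H3K4me1 slot grid")
  }
  stopifnot(chrom_length > 0, n_chromosomes >= 1,
            all(unlist(n_samples_per_class) >= 1),
            cluster_order_range[1] >= 2,
            cluster_order_range[2] >= cluster_order_range[1],
            intra_cluster_gap$mean / background_gap$mean <= 0.1,
            bivalent_fraction >= 0, bivalent_fraction <= 1,
            boundary_bias >= 0, boundary_bias <= 1,
            expression_suppression >= 0, expression_suppression <= 1,
            coverage_fold_primitive >= 1,
            peak_length$min > 0, intra_cluster_gap$min > 0,
            background_gap$min > intra_cluster_gap$max)
  structure(cfg, class = "sim_config")
}

# clamped-normal draw
.tnorm <- function(n, spec) {
  round(pmin(pmax(rnorm(n, spec$mean, spec$sd), spec$min), spec$max))
}

# deterministic substream seeding: fixed offsets so adding samples or marks
# never reshuffles existing ones
.substream <- function(seed, stream) {
  set.seed((as.integer(seed) + 8191L * as.integer(stream)) %% .Machine$integer.max)
}

.chrom_names <- function(cfg) sprintf("chr%d", seq_len(cfg$n_chromosomes))

# fixed slot grid (cluster anchor positions) for one mark
.slot_grid <- function(cfg, mark) {
  spacing <- cfg$chrom_length / (cfg$slots_per_chrom + 2)
  offset <- if (cfg$marks[[mark]] == "repressive") round(spacing / 2) else 0
  hard_span <- cfg$cluster_order_range[2] * cfg$peak_length$max +
    (cfg$cluster_order_range[2] - 1) * cfg$intra_cluster_gap$max
  if (spacing < hard_span + 33000) {
    stop("infeasible packing: slot spacing ", round(spacing),
         " bp cannot hold a maximal cluster (", hard_span,
         " bp) plus margins; increase chrom_length or reduce cluster sizes")
  }
  do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(ci) {
    data.frame(slot = paste0("c", ci, "s", seq_len(cfg$slots_per_chrom)),
               chrom = .chrom_names(cfg)[ci],
               pos = round(offset + seq_len(cfg$slots_per_chrom) * spacing))
  }))
}

.sample_table <- function(cfg) {
  do.call(rbind, lapply(names(cfg$n_samples_per_class), function(cls) {
    n <- cfg$n_samples_per_class[[cls]]
    tis <- rep(cfg$tissues[[cls]], length.out = n)
    tis <- sort(tis)
    idx <- stats::ave(seq_along(tis), tis, FUN = seq_along)
    data.frame(sample_id = sprintf("%s_%s_%d", substr(cls, 1, 4), tis, idx),
               cell_type = sprintf("%s_line%d", tis, idx),
               tissue = tis, class = cls, stringsAsFactors = FALSE)
  }))
}

# one planted cluster: peak starts/ends (0-based half-open) anchored at pos
.gen_cluster <- function(cfg, pos, order) {
  len <- .tnorm(order, cfg$peak_length)
  gap <- .tnorm(order - 1L, cfg$intra_cluster_gap)
  starts <- pos + c(0, cumsum(len[-order] + gap))
  data.frame(start = starts, end = starts + len)
}

#' Simulate a synthetic cohort with planted ground truth
#'
#' Writes per-sample per-mark peak BEDs, per-sample signal tracks (bedGraph)
#' for H3K4me1, H3K27me3 and H3K9me3, a cohort TAD-boundary BED, TF
#' binding-site BEDs (CTCF, RAD21, ZNF143 enriched in bivalent clusters; YY1
#' uniform), gene TSS annotations, an expression table, a gene-set GMT and a
#' sample-metadata TSV under `out_dir`, and returns the planted truth.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config a [sim_config()] object
#' @param out_dir output directory (created)
#' @return an object of class `planted_truth`: list with `clusters` (planted
#'   cluster table with Order and bivalency flags), `genes`, `boundaries`,
#'   `metadata`, `files` (all emitted paths), `config`
#' @export
simulate_cohort <- function(config = sim_config(), out_dir) {
  cfg <- config
  samples <- .sample_table(cfg)
  mark_names <- names(cfg$marks)
  grids <- lapply(mark_names, function(m) .slot_grid(cfg, m))
  names(grids) <- mark_names

  # ---- cohort-level structure (streams 1..9) ----
  # tissue slot pools per mark
  pools <- list()
  for (mi in seq_along(mark_names)) {
    m <- mark_names[mi]
    grid <- grids[[m]]
    pools[[m]] <- list()
    all_tissues <- unlist(cfg$tissues)
    for (ti in seq_along(all_tissues)) {
      tis <- all_tissues[ti]
      cls <- if (tis %in% cfg$tissues$primitive) "primitive" else "differentiated"
      n_cl <- .n_clusters(cfg, m, cls)
      pool_size <- min(nrow(grid), ceiling(n_cl * 4 / 3))
      .substream(cfg$seed, 1000L + 50L * mi + ti)
      pools[[m]][[tis]] <- sort(sample(nrow(grid), pool_size))
    }
  }

  # bivalent slots: subset of the H3K4me1 grid common to both primitive pools
  k4_grid <- grids[["H3K4me1"]]
  prim_pools <- pools[["H3K4me1"]][cfg$tissues$primitive]
  common <- Reduce(intersect, prim_pools)
  n_biv <- round(cfg$bivalent_fraction *
                   min(lengths(prim_pools)))
  .substream(cfg$seed, 2L)
  bivalent_slots <- sort(sample(common, min(n_biv, length(common))))

  # TAD boundaries: biased toward bivalent slots + far background boundaries
  .substream(cfg$seed, 3L)
  biased <- bivalent_slots[runif(length(bivalent_slots)) < cfg$boundary_bias]
  bnd <- data.frame(chrom = k4_grid$chrom[biased],
                    pos = k4_grid$pos[biased] - round(runif(length(biased), 0, 8000)))
  non_biv <- setdiff(seq_len(nrow(k4_grid)), bivalent_slots)
  far <- sample(non_biv, min(cfg$n_background_boundaries, length(non_biv)))
  bnd <- rbind(bnd, data.frame(chrom = k4_grid$chrom[far],
                               pos = k4_grid$pos[far] - 30000))
  bnd <- bnd[order(bnd$chrom, bnd$pos), ]

  # TF sites: enriched TFs concentrate in bivalent slots, YY1 uniform
  tf_site_w <- 10L
  .substream(cfg$seed, 4L)
  tf_sites <- list()
  for (tf in c("CTCF", "RAD21", "ZNF143")) {
    inside <- do.call(rbind, lapply(bivalent_slots, function(si) {
      p <- sort(round(runif(cfg$tf_sites_per_bivalent_lock,
                            k4_grid$pos[si], k4_grid$pos[si] + 8000 - tf_site_w)))
      data.frame(chrom = k4_grid$chrom[si], start = p)
    }))
    bg <- data.frame(
      chrom = sample(.chrom_names(cfg), cfg$n_background_tf_sites, replace = TRUE),
      start = round(runif(cfg$n_background_tf_sites, 0, cfg$chrom_length - tf_site_w)))
    x <- rbind(inside, bg)
    tf_sites[[tf]] <- x[order(x$chrom, x$start), ]
  }
  tf_sites[["YY1"]] <- {
    x <- data.frame(
      chrom = sample(.chrom_names(cfg), cfg$n_uniform_tf_sites, replace = TRUE),
      start = round(runif(cfg$n_uniform_tf_sites, 0, cfg$chrom_length - tf_site_w)))
    x[order(x$chrom, x$start), ]
  }

  # genes: clustered near every H3K4me1 slot + far background genes
  .substream(cfg$seed, 5L)
  slot_genes <- do.call(rbind, lapply(seq_len(nrow(k4_grid)), function(si) {
    data.frame(chrom = k4_grid$chrom[si],
               tss = k4_grid$pos[si] + round(runif(cfg$genes_per_slot, -5000, 10000)),
               slot = k4_grid$slot[si], near_bivalent_slot = si %in% bivalent_slots)
  }))
  bg_slot <- sample(seq_len(nrow(k4_grid)), cfg$n_background_genes, replace = TRUE)
  bg_genes <- data.frame(chrom = k4_grid$chrom[bg_slot],
                         tss = k4_grid$pos[bg_slot] - round(runif(cfg$n_background_genes, 20000, 28000)),
                         slot = NA_character_, near_bivalent_slot = FALSE)
  genes <- rbind(slot_genes, bg_genes)
  genes <- genes[order(genes$chrom, genes$tss), ]
  genes$gene_id <- sprintf("G%04d", seq_len(nrow(genes)))
  genes$strand <- rep_len(c("+", "-"), nrow(genes))
  genes$base_expr <- rlnorm(nrow(genes), log(100), 0.4)

  # ---- per sample x mark peak layouts (streams 100+) ----
  clusters <- list()
  peaks <- list()
  for (si in seq_len(nrow(samples))) {
    for (mi in seq_along(mark_names)) {
      m <- mark_names[mi]
      grid <- grids[[m]]
      pool <- pools[[m]][[samples$tissue[si]]]
      n_cl <- .n_clusters(cfg, m, samples$class[si])
      .substream(cfg$seed, 100L + 40L * si + mi)
      chosen <- sort(sample(pool, min(n_cl, length(pool))))
      orders <- sample(seq.int(cfg$cluster_order_range[1], cfg$cluster_order_range[2]),
                       length(chosen), replace = TRUE)
      cl_peaks <- vector("list", length(chosen))
      cl_rec <- vector("list", length(chosen))
      for (k in seq_along(chosen)) {
        pk <- .gen_cluster(cfg, grid$pos[chosen[k]], orders[k])
        cl_peaks[[k]] <- data.frame(chrom = grid$chrom[chosen[k]], pk)
        cl_rec[[k]] <- data.frame(
          sample_id = samples$sample_id[si], mark = m,
          chrom = grid$chrom[chosen[k]], start = pk$start[1], end = pk$end[orders[k]],
          order = orders[k], slot = grid$slot[chosen[k]],
          bivalent = m == "H3K4me1" && samples$class[si] == "primitive" &&
            chosen[k] %in% bivalent_slots)
      }
      # unclustered background singletons at fixed singleton anchors
      spacing <- cfg$chrom_length / (cfg$slots_per_chrom + 2)
      sing <- do.call(rbind, lapply(.chrom_names(cfg), function(ch) {
        anchors <- grid$pos[grid$chrom == ch][seq_len(cfg$singletons_per_chrom)] - 30000
        st <- anchors + round(runif(length(anchors), -2000, 2000))
        data.frame(chrom = ch, start = st,
                   end = st + .tnorm(length(st), cfg$peak_length))
      }))
      pk_all <- rbind(do.call(rbind, cl_peaks), sing)
      if (any(pk_all$end > cfg$chrom_length)) {
        stop("infeasible packing: a planted peak exceeds chrom_length")
      }
      pk_all <- pk_all[order(pk_all$chrom, pk_all$start), ]
      key <- paste(samples$sample_id[si], m, sep = "__")
      peaks[[key]] <- pk_all
      clusters[[key]] <- do.call(rbind, cl_rec)
    }
  }
  clusters <- do.call(rbind, clusters)
  rownames(clusters) <- NULL

  # ---- write files ----
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("peaks", "signal", "tf", "genes")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  files <- list(peaks = list(), signal = list(), tf = list())
  for (key in names(peaks)) {
    p <- file.path(out_dir, "peaks", paste0(key, ".bed"))
    write.table(peaks[[key]], p, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    files$peaks[[key]] <- p
  }

  # signal tracks (2 kb bins): elevated over the relevant planted spans
  signal_marks <- intersect(c("H3K4me1", "H3K27me3", "H3K9me3"), mark_names)
  for (si in seq_len(nrow(samples))) {
    sid <- samples$sample_id[si]
    for (m in signal_marks) {
      spans <- .signal_spans(cfg, m, sid, samples$class[si], clusters,
                             k4_grid, bivalent_slots)
      .substream(cfg$seed, 5000L + 40L * si + match(m, mark_names))
      track <- .binned_track(cfg, spans)
      p <- file.path(out_dir, "signal", paste0(sid, "__", m, ".bedgraph"))
      write.table(track, p, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
      files$signal[[paste(sid, m, sep = "__")]] <- p
    }
  }

  files$tads <- file.path(out_dir, "tads.bed")
  write.table(data.frame(bnd$chrom, bnd$pos, bnd$pos + 1L), files$tads,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (tf in names(tf_sites)) {
    p <- file.path(out_dir, "tf", paste0(tf, ".bed"))
    write.table(data.frame(tf_sites[[tf]]$chrom, tf_sites[[tf]]$start,
                           tf_sites[[tf]]$start + tf_site_w),
                p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    files$tf[[tf]] <- p
  }

  files$tss <- file.path(out_dir, "genes", "tss.bed")
  write.table(data.frame(genes$chrom, genes$tss, genes$tss + 1L, genes$gene_id,
                         0L, genes$strand),
              files$tss, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  # expression: one column per sample; suppression where the TSS is within
  # 10 kb of one of that sample's bivalent clusters
  .substream(cfg$seed, 6L)
  expr <- data.frame(gene_id = genes$gene_id)
  for (si in seq_len(nrow(samples))) {
    sid <- samples$sample_id[si]
    val <- genes$base_expr * rlnorm(nrow(genes), 0, 0.3)
    biv <- clusters[clusters$sample_id == sid & clusters$bivalent, , drop = FALSE]
    if (nrow(biv) > 0L) {
      supp <- .tss_near_spans(genes, biv, 10000)
      val[supp] <- val[supp] * cfg$expression_suppression
    }
    expr[[sid]] <- round(val, 3)
  }
  files$expression <- file.path(out_dir, "genes", "expression.tsv")
  write.table(expr, files$expression, sep = "\t", quote = FALSE, row.names = FALSE)

  files$metadata <- file.path(out_dir, "metadata.tsv")
  write.table(samples, files$metadata, sep = "\t", quote = FALSE, row.names = FALSE)

  # gene sets: bivalent-proximal genes, background genes, random mixture
  files$gmt <- file.path(out_dir, "genesets.gmt")
  .substream(cfg$seed, 7L)
  sets <- list(
    STEM_DIFFERENTIATION = genes$gene_id[genes$near_bivalent_slot],
    HOUSEKEEPING = genes$gene_id[is.na(genes$slot)],
    RANDOM_SET = sort(sample(genes$gene_id, 40)))
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1)), files$gmt)

  structure(list(clusters = clusters, genes = genes,
                 boundaries = bnd, bivalent_slots = k4_grid$slot[bivalent_slots],
                 metadata = samples, files = files, config = cfg,
                 out_dir = out_dir),
            class = "planted_truth")
}

.n_clusters <- function(cfg, mark, class) {
  if (cfg$marks[[mark]] == "repressive") return(cfg$n_repressive_clusters)
  if (class == "primitive") return(cfg$n_clusters_per_sample)
  max(2L, round(cfg$n_clusters_per_sample / cfg$coverage_fold_primitive))
}

# spans over which a sample's signal track for `mark` is elevated
.signal_spans <- function(cfg, mark, sample_id, class, clusters, k4_grid, bivalent_slots) {
  own <- clusters[clusters$sample_id == sample_id & clusters$mark == mark, , drop = FALSE]
  spans <- own[, c("chrom", "start", "end")]
  if (mark == "H3K27me3") {
    biv <- clusters[clusters$sample_id == sample_id & clusters$bivalent, , drop = FALSE]
    spans <- rbind(spans, biv[, c("chrom", "start", "end")])
  }
  if (mark == "H3K9me3" && class == "differentiated" && length(bivalent_slots) > 0L) {
    # the bivalent-to-H3K9me3 transition: repressive signal appears over the
    # (former) bivalent slots in differentiated cells
    spans <- rbind(spans, data.frame(chrom = k4_grid$chrom[bivalent_slots],
                                     start = k4_grid$pos[bivalent_slots],
                                     end = k4_grid$pos[bivalent_slots] + 15000))
  }
  spans
}

# step-function track: fixed bins, background noise, elevated over spans
.binned_track <- function(cfg, spans) {
  out <- lapply(.chrom_names(cfg), function(ch) {
    starts <- seq(0L, cfg$chrom_length - cfg$signal_bin, by = cfg$signal_bin)
    val <- cfg$background_signal * pmax(rnorm(length(starts), 1, 0.05), 0.05)
    sp <- spans[spans$chrom == ch, , drop = FALSE]
    if (nrow(sp) > 0L) {
      hit <- rep(FALSE, length(starts))
      for (r in seq_len(nrow(sp))) {
        hit <- hit | (starts < sp$end[r] & (starts + cfg$signal_bin) > sp$start[r])
      }
      val[hit] <- cfg$bivalent_signal_fold * cfg$background_signal *
        pmax(rnorm(sum(hit), 1, 0.05), 0.05)
    }
    data.frame(chrom = ch, start = starts, end = starts + cfg$signal_bin,
               value = round(val, 4))
  })
  do.call(rbind, out)
}

# genes whose TSS lies within `window` bp of any span (0-based convention:
# distance 0 inside, else min(|t - s|, |t - (e-1)|))
.tss_near_spans <- function(genes, spans, window) {
  near <- rep(FALSE, nrow(genes))
  for (r in seq_len(nrow(spans))) {
    on_chrom <- genes$chrom == spans$chrom[r]
    t <- genes$tss
    d <- pmax(spans$start[r] - t, t - (spans$end[r] - 1), 0)
    near <- near | (on_chrom & d <= window)
  }
  near
}

#' Summarize a planted truth
#'
#' @param truth a `planted_truth` from [simulate_cohort()]
#' @return data.frame: per sample x mark, the number of planted clusters,
#'   planted coverage in bp and planted bivalent-cluster count
#' @export
truth_report <- function(truth) {
  stopifnot(inherits(truth, "planted_truth"))
  cl <- truth$clusters
  if (is.null(cl) || nrow(cl) == 0L) {
    return(data.frame(sample_id = character(0), mark = character(0),
                      n_clusters = integer(0), planted_bp = numeric(0),
                      n_bivalent = integer(0)))
  }
  agg <- stats::aggregate(cbind(n_clusters = rep(1L, nrow(cl)),
                                planted_bp = cl$end - cl$start,
                                n_bivalent = as.integer(cl$bivalent)),
                          by = list(sample_id = cl$sample_id, mark = cl$mark), FUN = sum)
  agg[order(agg$sample_id, agg$mark), ]
}

#' Planted clusters of one sample and mark as a GRanges
#' @param truth a `planted_truth`
#' @param sample_id,mark selectors
#' @return GRanges of planted cluster spans (with `order`, `bivalent` mcols)
#' @export
truth_granges <- function(truth, sample_id, mark) {
  cl <- truth$clusters
  cl <- cl[cl$sample_id == sample_id & cl$mark == mark, , drop = FALSE]
  gr <- GenomicRanges::GRanges(cl$chrom,
                               IRanges::IRanges(start = cl$start + 1, end = cl$end))
  mcols(gr)$order <- cl$order
  mcols(gr)$bivalent <- cl$bivalent
  mcols(gr)$slot <- cl$slot
  sort_intervals(gr)
}
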