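#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqlevels seqlevels<- seqnames seqlevelsInUse
#' @importFrom stats rnorm runif rlnorm setNames
#' @importFrom utils read.delim write.table
NULL

# All on-disk interval formats are 0-based half-open (BED convention); in-memory
# intervals are GRanges (1-based closed).  The +1 shift happens only here.

.bed_to_granges <- function(chrom, start, end) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end))
  sort_intervals(gr)
}

#' Sort a GRanges lexicographically by chromosome, then by start
#'
#' Chromosome order is lexicographic; no genome build is assumed.
#' @param gr a GRanges
#' @return the sorted GRanges
#' @export
sort_intervals <- function(gr) {
  seqlevels(gr) <- sort(seqlevels(gr))
  sort(gr)
}

#' Read a BED file of genomic intervals
#'
#' Reads a 3+ column tab-separated BED file into a sorted `GRanges`.
#' Coordinates in the file are 0-based half-open; the returned object uses the
#' usual 1-based closed GRanges convention.  Extra columns are ignored.
#'
#' @param path path to a BED file
#' @param merge if `TRUE`, overlapping and book-ended intervals are unioned at
#'   load time (required by the LOCK caller, which assumes disjoint elements)
#' @param label free-text label stored in `metadata(x)$label`
#' @return a sorted `GRanges`; empty file gives an empty `GRanges`
#' @export
read_bed <- function(path, merge = FALSE, label = basename(path)) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    metadata(gr)$label <- label
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1L], " in '", path,
         "': fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad) > 0L) {
    stop("malformed BED line ", bad[1L], " in '", path, "': non-numeric coordinates")
  }
  bad <- which(end <= start | start < 0)
  if (length(bad) > 0L) {
    stop("invalid interval on line ", bad[1L], " in '", path,
         "': need 0 <= start < end")
  }
  gr <- .bed_to_granges(chrom, start, end)
  if (merge) gr <- GenomicRanges::reduce(gr)
  metadata(gr)$label <- label
  gr
}

#' Read a bedGraph file into a signal track
#'
#' A signal track is a step function over the genome: disjoint segments, each
#' with a signal value per bp.  `depth` is the total signal, i.e.
#' sum(value * segment length), in signal x bp units.
#'
#' @param path path to a 4-column bedGraph file
#' @return an object of class `signal_track` with elements `segments`
#'   (GRanges with a `value` metadata column) and `depth`
#' @export
read_bedgraph <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(signal_track(GenomicRanges::GRanges(), numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop("malformed bedGraph line ", which(nf < 4L)[1L], " in '", path,
         "': fewer than 4 columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4L)))
  if (anyNA(value) || any(!is.finite(value))) {
    stop("non-numeric or non-finite value column in '", path, "' (line ",
         which(!is.finite(value))[1L], ")")
  }
  bad <- which(!is.finite(start) | !is.finite(end) | end <= start | start < 0)
  if (length(bad) > 0L) {
    stop("invalid segment on line ", bad[1L], " in '", path, "'")
  }
  ord <- order(chrom, start)
  gr <- GenomicRanges::GRanges(chrom[ord],
                               IRanges::IRanges(start = start[ord] + 1L, end = end[ord]))
  mcols(gr)$value <- value[ord]
  gr <- sort_intervals(gr)
  cov <- GenomicRanges::reduce(gr)
  if (sum(GenomicRanges::width(cov)) != sum(GenomicRanges::width(gr))) {
    stop("overlapping segments in bedGraph '", path, "'")
  }
  signal_track(gr)
}

#' Construct a signal track from a segments GRanges
#'
#' @param segments GRanges with a numeric `value` metadata column
#' @param value optional value vector if `segments` lacks a `value` column
#' @return a `signal_track` object
#' @export
signal_track <- function(segments, value = NULL) {
  if (!is.null(value)) mcols(segments)$value <- value
  if (length(segments) > 0L && is.null(mcols(segments)$value)) {
    stop("signal track segments need a 'value' column")
  }
  depth <- if (length(segments) == 0L) 0 else
    sum(as.numeric(GenomicRanges::width(segments)) * mcols(segments)$value)
  structure(list(segments = segments, depth = depth), class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", length(x$segments), "segments, depth =",
      format(x$depth, big.mark = ","), "signal*bp\n")
  invisible(x)
}

#' Write a signal track as bedGraph
#' @param track a `signal_track`
#' @param path output path
#' @export
write_bedgraph <- function(track, path) {
  seg <- track$segments
  df <- data.frame(chrom = as.character(seqnames(seg)),
                   start = GenomicRanges::start(seg) - 1L,
                   end = GenomicRanges::end(seg),
                   value = mcols(seg)$value)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' GMT dialect: one set per line; fields are set name, description, then gene
#' ids, tab-separated.  Genes are deduplicated within a set.
#'
#' @param path path to a GMT file
#' @return a named list of character vectors of gene ids
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(setNames(list(), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name in '", path, "': ", nm[duplicated(nm)][1L])
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- nm
  sets
}

#' Write a generic GRanges as BED (0-based half-open)
#' @param gr GRanges
#' @param path output path
#' @param name optional name column
#' @param score optional score column
#' @export
write_bed <- function(gr, path, name = NULL, score = NULL) {
  if (length(gr) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  if (!is.null(name)) {
    df$name <- name
    df$score <- if (is.null(score)) 0 else score
    df$strand <- "."
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a LOCK set as BED6
#'
#' The score column carries the Order (member peak count) of each LOCK.
#' The written intervals round-trip through [read_bed()] to identical
#' coordinates.
#'
#' @param locks a `lock_set` from [call_locks()]
#' @param path output path
#' @export
write_locks_bed <- function(locks, path) {
  stopifnot(inherits(locks, "lock_set"))
  gr <- locks$locks
  write_bed(gr, path,
            name = if (length(gr)) paste0("LOCK_", seq_along(gr)) else NULL,
            score = if (length(gr)) mcols(gr)$order else NULL)
}

#' Read a sample-metadata table
#'
#' Tab-separated with columns `sample_id`, `cell_type`, `tissue`, `class`;
#' `class` must be one of primitive, ES-derived, differentiated.
#'
#' @param path path to the TSV
#' @return a data.frame
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_type", "tissue", "class")
  if (!all(need %in% names(md))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  ok <- md$class %in% c("primitive", "ES-derived", "differentiated")
  if (!all(ok)) {
    stop("unknown class label(s): ", paste(unique(md$class[!ok]), collapse = ", "))
  }
  md
}

#' Read gene TSS annotations from BED6
#'
#' The name column is the gene id; the interval start (0-based) is taken as the
#' TSS position.
#'
#' @param path path to a BED6 file
#' @return data.frame with columns gene_id, chrom, tss, strand
#' @export
read_tss_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("TSS BED needs at least 4 columns (name = gene id)")
  out <- data.frame(gene_id = as.character(df[[4L]]),
                    chrom = as.character(df[[1L]]),
                    tss = as.numeric(df[[2L]]),
                    strand = if (ncol(df) >= 6L) as.character(df[[6L]]) else "+",
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id)) stop("duplicate gene_id in TSS annotation")
  if (any(out$tss < 0)) stop("negative TSS position")
  out
}

#' Read an expression table
#'
#' Tab-separated, first column `gene_id`, one numeric column per sample /
#' cell type.
#'
#' @param path path to the TSV
#' @return data.frame with rownames = gene_id
#' @export
read_expression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "gene_id") stop("expression table must start with a gene_id column")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in expression table")
  rownames(df) <- df$gene_id
  df
}
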