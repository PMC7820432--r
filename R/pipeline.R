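# Orchestration: load a cohort from disk, run every analysis stage in
# dependency order, and record a manifest.  Stages are pure functions of
# (inputs, config, seed); rerunning with the same config and seed reproduces
# every output byte for byte.

#' Load a cohort directory
#'
#' Expects the layout written by [simulate_cohort()]: `peaks/<sample>__<mark>.bed`,
#' `signal/<sample>__<mark>.bedgraph`, `tads.bed`, `tf/<TF>.bed`,
#' `genes/tss.bed`, `genes/expression.tsv`, `genesets.gmt`, `metadata.tsv`.
#' Absent optional components are left NULL.
#'
#' @param dir cohort directory
#' @return list of class `cohort`: metadata, peak_files, signal_files,
#'   tad_file, tf_files, tss_file, expression_file, gmt_file
#' @export
load_cohort <- function(dir) {
  stopifnot(dir.exists(dir))
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_path)) stop("cohort has no metadata.tsv: ", dir)
  metadata <- read_metadata(meta_path)
  parse_keyed <- function(subdir, ext) {
    fs <- list.files(file.path(dir, subdir), pattern = paste0("\\.", ext, "$"),
                     full.names = TRUE)
    if (length(fs) == 0L) return(NULL)
    keys <- sub(paste0("\\.", ext, "$"), "", basename(fs))
    parts <- strsplit(keys, "__", fixed = TRUE)
    data.frame(sample_id = vapply(parts, `[[`, character(1), 1L),
               mark = vapply(parts, `[[`, character(1), 2L),
               path = fs, stringsAsFactors = FALSE)
  }
  tf_dir <- file.path(dir, "tf")
  tf_files <- if (dir.exists(tf_dir)) {
    fs <- list.files(tf_dir, pattern = "\\.bed$", full.names = TRUE)
    stats::setNames(fs, sub("\\.bed$", "", basename(fs)))
  } else NULL
  opt <- function(p) if (file.exists(p)) p else NULL
  structure(list(
    dir = dir, metadata = metadata,
    peak_files = parse_keyed("peaks", "bed"),
    signal_files = parse_keyed("signal", "bedgraph"),
    tad_file = opt(file.path(dir, "tads.bed")),
    tf_files = tf_files,
    tss_file = opt(file.path(dir, "genes", "tss.bed")),
    expression_file = opt(file.path(dir, "genes", "expression.tsv")),
    gmt_file = opt(file.path(dir, "genesets.gmt"))), class = "cohort")
}

#' Call LOCKs for every sample and mark of a cohort
#'
#' @param cohort a `cohort` from [load_cohort()]
#' @param params a [caller_params()] object
#' @param marks restrict to these marks (default: all in the cohort)
#' @return list of class `cohort_locks`: `locks[[mark]][[sample_id]]` =
#'   `lock_set`, `peaks[[mark]][[sample_id]]` = merged peak GRanges
#' @export
call_cohort_locks <- function(cohort, params = caller_params(), marks = NULL) {
  pf <- cohort$peak_files
  if (is.null(pf)) stop("cohort has no peak files")
  if (is.null(marks)) marks <- sort(unique(pf$mark))
  locks <- list()
  peaks <- list()
  for (m in marks) {
    rows <- pf[pf$mark == m, , drop = FALSE]
    rows <- rows[match(intersect(cohort$metadata$sample_id, rows$sample_id),
                       rows$sample_id), , drop = FALSE]
    locks[[m]] <- list()
    peaks[[m]] <- list()
    for (r in seq_len(nrow(rows))) {
      pk <- read_bed(rows$path[r], merge = TRUE)
      peaks[[m]][[rows$sample_id[r]]] <- pk
      locks[[m]][[rows$sample_id[r]]] <-
        call_locks(pk, params, sample_id = rows$sample_id[r], mark = m)
    }
  }
  structure(list(locks = locks, peaks = peaks), class = "cohort_locks")
}

#' Classify cohort samples from their LOCKs, one report per mark
#'
#' @param cohort_locks a `cohort_locks`
#' @param metadata cohort metadata (defines sample order and labels)
#' @param label_col metadata column used as the class label
#' @param method similarity flavour, see [nn_classify_loo()]
#' @return named list: mark -> `classification_report`
#' @export
classify_cohort <- function(cohort_locks, metadata, label_col = "class",
                            method = "bp") {
  lapply(cohort_locks$locks, function(per_sample) {
    ids <- intersect(metadata$sample_id, names(per_sample))
    labels <- metadata[[label_col]][match(ids, metadata$sample_id)]
    nn_classify_loo(per_sample[ids], labels, method = method)
  })
}

#' Coverage records for all marks of a cohort
#' @param cohort_locks a `cohort_locks`
#' @return data.frame as from [coverage_records()], all marks stacked
#' @export
cohort_coverage <- function(cohort_locks) {
  do.call(rbind, lapply(names(cohort_locks$locks), function(m) {
    coverage_records(cohort_locks$locks[[m]], cohort_locks$peaks[[m]], m)
  }))
}

#' Bivalency scoring of one sample's active-mark LOCKs
#'
#' Integrates the sample's repressive-signal track over its active-mark LOCKs
#' and individual elements, normalizes LOCK signal to the element median, and
#' assigns high/intermediate/low categories.
#'
#' @param cohort a `cohort`
#' @param cohort_locks a `cohort_locks`
#' @param sample_id sample to score
#' @param active_mark mark whose LOCKs are scored (default H3K4me1)
#' @param signal_mark repressive signal mark (default H3K27me3)
#' @return data.frame: region_id, width, raw, per_bp, normalized, category,
#'   with the LOCK GRanges as attribute `locks`
#' @export
bivalency_scores <- function(cohort, cohort_locks, sample_id,
                             active_mark = "H3K4me1", signal_mark = "H3K27me3") {
  sf <- cohort$signal_files
  path <- sf$path[sf$sample_id == sample_id & sf$mark == signal_mark]
  if (length(path) != 1L) {
    stop("no ", signal_mark, " signal track for sample ", sample_id)
  }
  track <- read_bedgraph(path)
  lockset <- cohort_locks$locks[[active_mark]][[sample_id]]
  elements <- cohort_locks$peaks[[active_mark]][[sample_id]]
  if (is.null(lockset)) stop("no ", active_mark, " locks for sample ", sample_id)
  lock_ov <- signal_over_intervals(track, lockset$locks)
  elem_ov <- signal_over_intervals(track, elements)
  lock_ov <- normalize_to_individual(lock_ov, elem_ov)
  lock_ov$category <- categorize_h3k27me3(lock_ov$normalized)
  attr(lock_ov, "locks") <- lockset$locks
  lock_ov
}

.stage_names <- c("simulate", "call_locks", "catalogue_classify", "coverage",
                  "gene_link", "bivalency", "enrichment")

.default_pipeline_config <- function() {
  list(seed = 1L,
       simulate = list(enabled = TRUE),
       inputs = list(dir = NULL),
       stages = list(call_locks = TRUE, catalogue_classify = TRUE,
                     coverage = TRUE, gene_link = TRUE, bivalency = TRUE,
                     enrichment = TRUE),
       caller = list(),
       reference_class = "primitive",
       active_mark = "H3K4me1", signal_mark = "H3K27me3",
       association_window = 10000)
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

# pre-flight validation: every enabled stage must find its inputs, before any
# stage runs
.preflight <- function(cfg, cohort_dir) {
  if (isTRUE(cfg$simulate$enabled)) return(invisible(TRUE))
  if (is.null(cfg$inputs$dir)) stop("config field 'inputs.dir' is required when simulate is disabled")
  if (!dir.exists(cfg$inputs$dir)) stop("inputs.dir does not exist: ", cfg$inputs$dir)
  need <- list(
    call_locks = file.path(cfg$inputs$dir, "peaks"),
    catalogue_classify = file.path(cfg$inputs$dir, "metadata.tsv"),
    coverage = file.path(cfg$inputs$dir, "metadata.tsv"),
    gene_link = file.path(cfg$inputs$dir, "genes", "tss.bed"),
    bivalency = file.path(cfg$inputs$dir, "signal"),
    enrichment = file.path(cfg$inputs$dir, "tads.bed"))
  for (st in names(need)) {
    if (isTRUE(cfg$stages[[st]]) && !file.exists(need[[st]])) {
      stop("stage '", st, "' is enabled but its input is missing: ", need[[st]])
    }
  }
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: cohort simulation (or loading), LOCK
#' calling, catalogue building and classification, coverage comparison, gene
#' association and expression comparison, bivalency scoring, and TAD-boundary
#' / regulator / pathway enrichment.  Writes per-stage tables under
#' `out_dir/results` and a JSON manifest.
#'
#' @param config a YAML file path or a nested list (see
#'   the methods vignette); missing entries take defaults
#' @param out_dir output directory
#' @return the run manifest (list), invisibly written to
#'   `out_dir/manifest.json`
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- .default_pipeline_config()
  config_hash <- NA_character_
  if (is.character(config)) {
    config_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  if (!is.null(config)) cfg <- .merge_config(cfg, config)
  if (is.na(config_hash)) {
    tmp <- tempfile()
    yaml::write_yaml(cfg, tmp)
    config_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
  }
  .preflight(cfg, out_dir)
  dir.create(file.path(out_dir, "results"), recursive = TRUE, showWarnings = FALSE)
  res_dir <- file.path(out_dir, "results")
  manifest <- list(config_hash = config_hash, seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("lockscape")),
                   stages = list())
  note <- function(stage, outputs) {
    manifest$stages[[stage]] <<- list(outputs = outputs, status = "ok")
  }

  # 1: cohort
  if (isTRUE(cfg$simulate$enabled)) {
    sim_args <- cfg$simulate
    sim_args$enabled <- NULL
    sim_args$seed <- cfg$seed
    truth <- simulate_cohort(do.call(sim_config, sim_args),
                             file.path(out_dir, "cohort"))
    cohort_dir <- file.path(out_dir, "cohort")
    tr_path <- file.path(res_dir, "planted_truth.tsv")
    write.table(truth_report(truth), tr_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    note("simulate", c(cohort_dir, tr_path))
  } else {
    truth <- NULL
    cohort_dir <- cfg$inputs$dir
    note("simulate", cohort_dir)
  }
  cohort <- load_cohort(cohort_dir)

  # 2: LOCK calling
  params <- do.call(caller_params, cfg$caller)
  cl <- call_cohort_locks(cohort, params)
  lock_dir <- file.path(res_dir, "locks")
  dir.create(lock_dir, showWarnings = FALSE)
  lock_paths <- character(0)
  for (m in names(cl$locks)) {
    for (sid in names(cl$locks[[m]])) {
      p <- file.path(lock_dir, paste0(sid, "__", m, ".bed"))
      write_locks_bed(cl$locks[[m]][[sid]], p)
      lock_paths <- c(lock_paths, p)
    }
  }
  note("call_locks", lock_paths)

  # 3: catalogue + classification
  if (isTRUE(cfg$stages$catalogue_classify)) {
    reports <- classify_cohort(cl, cohort$metadata)
    cls_tab <- do.call(rbind, lapply(names(reports), function(m) {
      data.frame(mark = m, average_mcc = reports[[m]]$average_mcc,
                 n_correct = sum(reports[[m]]$predicted == reports[[m]]$labels),
                 n = length(reports[[m]]$labels))
    }))
    p <- file.path(res_dir, "classification.tsv")
    write.table(cls_tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    note("catalogue_classify", p)
  }

  # 4: coverage comparison
  if (isTRUE(cfg$stages$coverage)) {
    records <- cohort_coverage(cl)
    cmp <- compare_groups(records, cohort$metadata)
    p1 <- file.path(res_dir, "coverage.tsv")
    p2 <- file.path(res_dir, "coverage_comparison.tsv")
    write.table(records, p1, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cmp, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    note("coverage", c(p1, p2))
  }

  rep_sample <- cohort$metadata$sample_id[
    cohort$metadata$class == cfg$reference_class][1L]

  # 5: gene association + expression comparison for the representative sample
  if (isTRUE(cfg$stages$gene_link)) {
    genes <- read_tss_bed(cohort$tss_file)
    lockset <- cl$locks[[cfg$active_mark]][[rep_sample]]
    assoc <- associate_genes(lockset$locks, genes, cfg$association_window)
    p <- file.path(res_dir, "gene_association.tsv")
    write.table(assoc, p, sep = "\t", quote = FALSE, row.names = FALSE)
    note("gene_link", p)
  }

  # 6: bivalency scoring for the representative sample
  if (isTRUE(cfg$stages$bivalency)) {
    biv <- bivalency_scores(cohort, cl, rep_sample,
                            active_mark = cfg$active_mark,
                            signal_mark = cfg$signal_mark)
    p <- file.path(res_dir, "bivalency.tsv")
    write.table(biv, p, sep = "\t", quote = FALSE, row.names = FALSE)
    note("bivalency", p)
  }

  # 7: enrichment (TAD boundaries, regulators, pathways)
  if (isTRUE(cfg$stages$enrichment)) {
    biv <- bivalency_scores(cohort, cl, rep_sample,
                            active_mark = cfg$active_mark,
                            signal_mark = cfg$signal_mark)
    locks_gr <- attr(biv, "locks")
    boundaries <- read_bed(cohort$tad_file)
    tad <- tad_boundary_enrichment(locks_gr, biv$category, boundaries)
    sites <- lapply(cohort$tf_files, read_bed)
    reg <- regulator_enrichment(sites, locks_gr, biv$category)
    outs <- character(0)
    p <- file.path(res_dir, "tad_enrichment.tsv")
    write.table(tad, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outs <- c(outs, p)
    p <- file.path(res_dir, "regulator_enrichment.tsv")
    write.table(reg, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outs <- c(outs, p)
    if (!is.null(cohort$gmt_file) && !is.null(cohort$tss_file)) {
      genes <- read_tss_bed(cohort$tss_file)
      high <- biv$category == "high"
      q_genes <- associate_genes(locks_gr[high], genes)$gene_id
      bg_genes <- associate_genes(locks_gr, genes)$gene_id
      path_res <- pathway_enrichment(q_genes, bg_genes, read_gmt(cohort$gmt_file))
      p <- file.path(res_dir, "pathway_enrichment.tsv")
      write.table(path_res, p, sep = "\t", quote = FALSE, row.names = FALSE)
      outs <- c(outs, p)
    }
    note("enrichment", outs)
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
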