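# Cross-sample LOCK catalogue, tissue assignment, and the Jaccard 1-NN
# leave-one-out classifier scored with the Matthews correlation coefficient.

#' Build a cross-sample LOCK catalogue for one mark
#'
#' Regions are the union-merge of all samples' LOCK intervals; the presence
#' matrix records, per sample and region, whether the sample has at least
#' 1 bp of LOCK overlap with the region.
#'
#' @param locksets list of `lock_set` objects (one per sample, same mark)
#' @param mark the histone mark; all locksets must agree
#' @return list of class `lock_catalogue`: `regions` (GRanges), `presence`
#'   (binary sample x region matrix), `mark`
#' @export
build_catalogue <- function(locksets, mark) {
  marks <- vapply(locksets, function(l) l$mark %||% mark, character(1))
  if (!all(marks == mark)) stop("lockset mark mismatch: expected ", mark)
  ids <- vapply(seq_along(locksets), function(i) {
    locksets[[i]]$sample_id %||% paste0("sample_", i)
  }, character(1))
  # unname: named arguments divert c() away from the GRanges method
  all_gr <- do.call(c, unname(lapply(locksets, function(l) {
    gr <- l$locks
    mcols(gr) <- NULL
    gr
  })))
  regions <- GenomicRanges::reduce(sort_intervals(all_gr))
  presence <- matrix(0L, nrow = length(locksets), ncol = length(regions),
                     dimnames = list(ids, NULL))
  for (i in seq_along(locksets)) {
    ov <- GenomicRanges::countOverlaps(regions, locksets[[i]]$locks)
    presence[i, ] <- as.integer(ov > 0)
  }
  structure(list(regions = regions, presence = presence, mark = mark),
            class = "lock_catalogue")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign catalogue regions to tissues
#'
#' A region is assigned to a tissue if it is present in strictly more than
#' `fraction` of that tissue's samples.
#'
#' @param catalogue a `lock_catalogue`
#' @param metadata data.frame with `sample_id` and `tissue`
#' @param fraction presence fraction that must be exceeded (default 0.5)
#' @return named list: tissue -> GRanges of assigned regions
#' @export
assign_tissue_locks <- function(catalogue, metadata, fraction = 0.5) {
  stopifnot(inherits(catalogue, "lock_catalogue"))
  ids <- rownames(catalogue$presence)
  missing <- setdiff(ids, metadata$sample_id)
  if (length(missing)) stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  out <- list()
  for (tis in unique(metadata$tissue)) {
    sids <- intersect(ids, metadata$sample_id[metadata$tissue == tis])
    if (length(sids) == 0L) {
      warning("tissue '", tis, "' has no samples in the catalogue; excluded")
      next
    }
    frac <- colMeans(catalogue$presence[sids, , drop = FALSE])
    out[[tis]] <- catalogue$regions[frac > fraction]
  }
  out
}

#' Base-pair Jaccard similarity of two interval sets
#'
#' bp(intersection) / bp(union); 0 when the union is empty.  Inputs should be
#' merged (reduced) interval sets; they are reduced defensively.
#'
#' @param a,b GRanges
#' @return a fraction in 0..1
#' @export
jaccard <- function(a, b) {
  a <- GenomicRanges::reduce(a)
  b <- GenomicRanges::reduce(b)
  # comparing sets on disjoint chromosome sets is legitimate (Jaccard 0);
  # silence the seqlevel-merge notice that union/intersect emit for it
  uni <- suppressWarnings(
    sum(as.numeric(GenomicRanges::width(GenomicRanges::union(a, b)))))
  if (uni == 0) return(0)
  int <- suppressWarnings(
    sum(as.numeric(GenomicRanges::width(GenomicRanges::intersect(a, b)))))
  int / uni
}

#' Matthews correlation coefficient from one-vs-rest confusion counts
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; defined as 0 when
#' any factor under the root is zero.
#'
#' @param tp,tn,fp,fn confusion counts
#' @return MCC in -1..1
#' @export
mcc <- function(tp, tn, fp, fn) {
  stopifnot(tp + tn + fp + fn >= 1)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Leave-one-out 1-nearest-neighbour classification of samples by LOCK
#' similarity
#'
#' Each sample is predicted as the label of its most similar other sample,
#' with similarity the base-pair interval Jaccard of the samples' LOCK sets
#' (default) or the Jaccard of catalogue presence vectors.  Ties resolve to
#' the smallest sample index.  Per-class MCC is computed one-vs-rest from the
#' leave-one-out confusion table; the average MCC is the unweighted mean over
#' classes.
#'
#' @param locksets list of `lock_set` objects (or plain GRanges), one per
#'   sample, in metadata order
#' @param labels character vector of class labels, one per sample
#' @param method `"bp"` (interval Jaccard) or `"presence"` (catalogue
#'   presence-vector Jaccard)
#' @param similarity optional precomputed similarity matrix (used for
#'   label-permutation tests); bypasses `method`
#' @return list of class `classification_report`: `predicted`, `per_class_mcc`,
#'   `average_mcc`, `confusion`, `nn_index`, `similarity`
#' @export
nn_classify_loo <- function(locksets, labels, method = c("bp", "presence"),
                            similarity = NULL) {
  method <- match.arg(method)
  n <- length(labels)
  if (n < 2L) stop("need at least 2 samples")
  if (length(unique(labels)) < 2L) stop("need at least 2 distinct labels")
  single <- names(which(table(labels) == 1L))
  if (length(single)) {
    warning("class(es) with a single sample can never be predicted correctly ",
            "under leave-one-out: ", paste(single, collapse = ", "))
  }
  if (is.null(similarity)) {
    sets <- lapply(locksets, function(l) {
      if (inherits(l, "lock_set")) l$locks else l
    })
    similarity <- matrix(1, n, n)
    if (method == "bp") {
      sets <- lapply(sets, GenomicRanges::reduce)
      for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
          similarity[i, j] <- similarity[j, i] <- jaccard(sets[[i]], sets[[j]])
        }
      }
    } else {
      pres <- do.call(rbind, lapply(sets, as.numeric))
      for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
          u <- sum(pres[i, ] > 0 | pres[j, ] > 0)
          s <- if (u == 0) 0 else sum(pres[i, ] > 0 & pres[j, ] > 0) / u
          similarity[i, j] <- similarity[j, i] <- s
        }
      }
    }
  }
  nn_index <- vapply(seq_len(n), function(i) {
    s <- similarity[i, ]
    s[i] <- -Inf
    which.max(s)  # ties -> smallest index
  }, integer(1))
  predicted <- labels[nn_index]
  classes <- sort(unique(labels))
  per_class <- vapply(classes, function(cl) {
    tp <- sum(predicted == cl & labels == cl)
    tn <- sum(predicted != cl & labels != cl)
    fp <- sum(predicted == cl & labels != cl)
    fn <- sum(predicted != cl & labels == cl)
    mcc(tp, tn, fp, fn)
  }, numeric(1))
  structure(list(predicted = predicted, labels = labels,
                 per_class_mcc = per_class,
                 average_mcc = mean(per_class),
                 confusion = table(truth = labels, predicted = factor(predicted, levels = classes)),
                 nn_index = nn_index, similarity = similarity),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("1-NN leave-one-out classification of", length(x$labels), "samples\n")
  cat("  average MCC:", round(x$average_mcc, 4), "\n")
  for (cl in names(x$per_class_mcc)) {
    cat("   ", cl, "MCC:", round(x$per_class_mcc[[cl]], 4), "\n")
  }
  invisible(x)
}

#' Label-permutation null for the 1-NN classifier
#'
#' Re-runs the leave-one-out prediction with permuted labels (the similarity
#' structure is kept fixed) and returns the average MCC of each permutation.
#'
#' @param report a `classification_report`
#' @param n_perm number of permutations
#' @return numeric vector of average MCCs, one per permutation
#' @export
permute_labels_mcc <- function(report, n_perm = 20L) {
  stopifnot(inherits(report, "classification_report"))
  vapply(seq_len(n_perm), function(p) {
    perm <- sample(report$labels)
    r <- nn_classify_loo(NULL, perm, similarity = report$similarity)
    r$average_mcc
  }, numeric(1))
}
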