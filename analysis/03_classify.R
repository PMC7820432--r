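#!/usr/bin/env Rscript
# Classify samples (primitive vs differentiated) with the 1-NN leave-one-out
# classifier on base-pair Jaccard similarity of LOCK sets, per mark, and
# contrast with a label-permutation null.
source("analysis/00_config.R")

cohort <- load_cohort(COHORT_DIR)
locks <- readRDS("scratch/cohort_locks.rds")

reports <- classify_cohort(locks, cohort$metadata)
set.seed(SEED + 1000L)
rows <- lapply(names(reports), function(m) {
  perm <- permute_labels_mcc(reports[[m]], 20L)
  data.frame(mark = m,
             average_mcc = reports[[m]]$average_mcc,
             accuracy = mean(reports[[m]]$predicted == reports[[m]]$labels),
             permuted_mcc_mean = mean(perm))
})
tab <- do.call(rbind, rows)
write.table(tab, file.path(RESULTS_DIR, "03_classification.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(tab, row.names = FALSE)

# per-tissue LOCK assignment from the catalogue (strict majority rule)
for (m in names(locks$locks)) {
  cat1 <- build_catalogue(locks$locks[[m]], m)
  per_tissue <- assign_tissue_locks(cat1, cohort$metadata)
  cat(m, ": catalogue of", length(cat1$regions), "regions;",
      paste(vapply(names(per_tissue), function(t)
        paste0(t, "=", length(per_tissue[[t]])), character(1)), collapse = " "),
      "tissue-assigned\n")
}
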