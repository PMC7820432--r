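#!/usr/bin/env Rscript
# Simulate the synthetic cohort: per-sample per-mark peak calls with planted
# domain structure, repressive-signal tracks, TAD boundaries, TF sites, genes
# and expression.  Writes the cohort under results/cohort and a summary of
# the planted truth.
source("analysis/00_config.R")

truth <- simulate_cohort(cohort_config(), COHORT_DIR)
saveRDS(truth, file.path("scratch", "planted_truth.rds"))  # scratch: not a deliverable

report <- truth_report(truth)
write.table(report, file.path(RESULTS_DIR, "01_planted_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

md <- truth$metadata
cat("Cohort:", nrow(md), "samples (",
    sum(md$class == "primitive"), "primitive,",
    sum(md$class == "differentiated"), "differentiated ) x",
    length(unique(report$mark)), "marks\n")
cat("Planted clusters:", sum(report$n_clusters),
    "; bivalent:", sum(report$n_bivalent), "\n")
agg <- aggregate(planted_bp ~ mark, report, sum)
print(agg)
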