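#!/usr/bin/env Rscript
# Hypergeometric enrichment with the workflow's custom backgrounds:
# H3K27me3-category LOCKs at TAD boundaries (background: all LOCKs),
# regulator binding in LOCK categories (bp-weighted urn), and pathway
# enrichment of high-category LOCK genes against all-LOCK genes.
source("analysis/00_config.R")

cohort <- load_cohort(COHORT_DIR)
locks <- readRDS("scratch/cohort_locks.rds")
md <- cohort$metadata
sid <- md$sample_id[md$class == "primitive"][1]

scores <- bivalency_scores(cohort, locks, sid)
locks_gr <- attr(scores, "locks")

tad <- tad_boundary_enrichment(locks_gr, scores$category,
                               read_bed(cohort$tad_file))
write.table(tad, file.path(RESULTS_DIR, "07_tad_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("TAD-boundary enrichment (", sid, "):\n")
print(tad[, c("category", "k", "n", "K", "N", "fdr")], row.names = FALSE)

sites <- lapply(cohort$tf_files, read_bed)
reg <- regulator_enrichment(sites, locks_gr, scores$category)
write.table(reg, file.path(RESULTS_DIR, "07_regulator_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nRegulator enrichment, high-H3K27me3 category:\n")
hi <- reg[reg$category == "high", ]
print(hi[, c("tf", "k", "K", "fdr")], row.names = FALSE)

genes <- read_tss_bed(cohort$tss_file)
q_genes <- associate_genes(locks_gr[scores$category == "high"], genes)$gene_id
bg_genes <- associate_genes(locks_gr, genes)$gene_id
paths <- pathway_enrichment(q_genes, bg_genes, read_gmt(cohort$gmt_file))
write.table(paths, file.path(RESULTS_DIR, "07_pathway_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nPathway enrichment of high-category LOCK genes:\n")
print(paths[, c("set", "k", "n", "K", "N", "fdr")], row.names = FALSE)
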