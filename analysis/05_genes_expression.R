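#!/usr/bin/env Rscript
# Associate genes with LOCKs by TSS distance (10 kb, anchored on the TSS)
# and compare expression of genes near bivalent vs active-only LOCKs in a
# primitive sample.
source("analysis/00_config.R")

cohort <- load_cohort(COHORT_DIR)
locks <- readRDS("scratch/cohort_locks.rds")
truth <- readRDS("scratch/planted_truth.rds")
genes <- read_tss_bed(cohort$tss_file)
expr <- read_expression(cohort$expression_file)

md <- cohort$metadata
sid <- md$sample_id[md$class == "primitive"][1]
lock_gr <- locks$locks[["H3K4me1"]][[sid]]$locks

assoc <- associate_genes(lock_gr, genes)
write.table(assoc, file.path(RESULTS_DIR, "05_gene_association.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Genes within 10 kb of", sid, "H3K4me1 LOCKs:",
    length(unique(assoc$gene_id)), "of", nrow(genes), "\n")

# planted bivalency flags for the called LOCKs (truth-matched)
tg <- truth_granges(truth, sid, "H3K4me1")
ov <- GenomicRanges::findOverlaps(lock_gr, tg)
flags <- rep(FALSE, length(lock_gr))
flags[S4Vectors::queryHits(ov)] <-
  S4Vectors::mcols(tg)$bivalent[S4Vectors::subjectHits(ov)]

g_biv <- associate_genes(lock_gr[flags], genes)$gene_id
g_act <- setdiff(associate_genes(lock_gr[!flags], genes)$gene_id, g_biv)
res <- compare_expression(g_biv, g_act, expr, sid)
out <- data.frame(sample_id = sid, n_bivalent_genes = res$n_a,
                  n_active_genes = res$n_b, median_bivalent = res$median_a,
                  median_active = res$median_b, direction = res$direction,
                  p_value = res$p_value)
write.table(out, file.path(RESULTS_DIR, "05_expression_comparison.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf(paste0("Expression near bivalent vs active-only LOCKs in %s: ",
                   "medians %.1f vs %.1f (%s), rank-sum p = %.3g\n"),
            sid, res$median_a, res$median_b, res$direction, res$p_value))
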