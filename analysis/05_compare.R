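#!/usr/bin/env Rscript
# Stage 5 -- detection breadth, overlap, tiers, correlation, PCA, ranks.
#
# Consumes the per-workflow protein matrices written by stages 2-3.

library(csfbench)

ch <- load_cohort("results/cohort")
out <- "results/pipeline"
wf <- unique(ch$sample_sheet$method)
mats <- stats::setNames(lapply(wf, function(w) {
  read_quant_matrix(file.path(out, sprintf("protein_matrix_%s.tsv", w)),
                    ch$sample_sheet)
}), wf)
dc <- detection_counts(mats)
ms <- membership_sets(mats)
tiers <- do.call(rbind, lapply(wf, function(w) {
  cbind(workflow = w, detection_tiers(mats[[w]])$tiers)
}))
combined <- combine_matrices(mats)
corr <- correlation_matrix(combined)
pca <- pca_scores(combined)
ra <- rank_abundance(combined, ch$gene_list)
utils::write.table(dc$per_workflow, file.path(out, "detection_medians.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ms$regions, file.path(out, "upset_regions.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(tiers, file.path(out, "detection_tiers.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cbind(sample_id = rownames(corr$r),
                         as.data.frame(corr$r)),
                   file.path(out, "correlation.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE, na = "")
utils::write.table(ra$ranking, file.path(out, "rank_abundance.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("union of %d proteins over %d workflows; PC1 %.1f%% of variance",
                ms$union_size, length(wf), 100 * pca$explained[1]))
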