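#!/usr/bin/env Rscript
# Stage 6 -- fraction-unique / fraction-elevated classification and
# subcellular over-representation.
#
# Elevated in W: against every other workflow, positive mean paired log2
# difference and BH-adjusted signed-rank p < 0.05 (family: per workflow
# pair across proteins; proteins detected in >= 50% of samples of both
# workflows; >= 4 complete patient pairs). Enriched set = unique union
# elevated, tested per subcellular category against the detected-anywhere
# background with Fisher's exact test and conditional-MLE odds ratios.

library(csfbench)

ch <- load_cohort("results/cohort")
out <- "results/pipeline"
wf <- unique(ch$sample_sheet$method)
mats <- stats::setNames(lapply(wf, function(w) {
  read_quant_matrix(file.path(out, sprintf("protein_matrix_%s.tsv", w)),
                    ch$sample_sheet)
}), wf)
res <- classify_fraction_proteins(mats)
utils::write.table(res$calls, file.path(out, "enrichment_calls.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE, na = "")
utils::write.table(res$comparisons,
                   file.path(out, "enrichment_comparisons.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE, na = "")
categories <- consolidate_locations(ch$annotations)
background <- sort(unique(unlist(lapply(mats, function(qm) {
  rownames(qm$values)[rowSums(!is.na(qm$values)) > 0]
}))))
for (w in wf) {
  set <- intersect(res$enriched[[w]], background)
  if (!length(set)) next
  tab <- ora(set, background, categories,
             attr(subcellular_scheme(), "analyzed"))
  utils::write.table(tab, file.path(out, sprintf("ora_%s.tsv", w)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%-8s %3d enriched proteins; top category %s (log2 OR %.2f)",
                  w, length(set), tab$category[which.min(tab$p)],
                  tab$log2_odds_ratio[which.min(tab$p)]))
}
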