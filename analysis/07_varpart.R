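#!/usr/bin/env Rscript
# Stage 7 -- variance partitioning.
#
# Per protein, log2 intensities across all workflows and patients are
# decomposed under y = mu + (1|method) + (1|patient) + e by EM-REML;
# fractions are summarized across proteins as percentages.

library(csfbench)

ch <- load_cohort("results/cohort")
out <- "results/pipeline"
wf <- unique(ch$sample_sheet$method)
mats <- stats::setNames(lapply(wf, function(w) {
  read_quant_matrix(file.path(out, sprintf("protein_matrix_%s.tsv", w)),
                    ch$sample_sheet)
}), wf)
long <- long_observations(mats)
fr <- fit_variance_components_all(long)
sm <- summarize_fractions(fr)
utils::write.table(fr, file.path(out, "variance_fractions.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE, na = "")
utils::write.table(sm, file.path(out, "variance_summary.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(sm))) {
  message(sprintf("%-9s median %5.1f%% (IQR %5.1f-%5.1f)", sm$component[i],
                  sm$median_pct[i], sm$q25_pct[i], sm$q75_pct[i]))
}
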