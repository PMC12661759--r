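#!/usr/bin/env Rscript
# Stage 8 -- nanoparticle-tracking-analysis size distributions.
#
# Dilution factors: 4 for the P150-EV fraction, 5 for P20-EV. Counts are
# normalized, technical-replicate videos summarized as mean +/- SE, and
# the two fractions merged on bin centers.

library(csfbench)

ch <- load_cohort("results/cohort")
out <- "results/pipeline"
dil <- c("P150-EV" = 4, "P20-EV" = 5)
dists <- list()
for (f in ch$nta_files) {
  fraction <- sub("^nta_(.*)-ExperimentSummary\\.csv$", "\\1", basename(f))
  dists[[fraction]] <- normalize_and_summarize(load_nta(f), dil[[fraction]],
                                               fraction)
  message(sprintf("%-8s total %.3g particles/mL over %d bins", fraction,
                  sum(dists[[fraction]]$concentration_mean),
                  nrow(dists[[fraction]])))
}
utils::write.table(do.call(rbind, dists), file.path(out, "nta_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE, na = "")
if (length(dists) >= 2) {
  utils::write.table(merge_distributions(dists[[1]], dists[[2]]),
                     file.path(out, "nta_merged.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
}
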