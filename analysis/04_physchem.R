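#!/usr/bin/env Rscript
# Stage 4 -- physicochemical bias profiling.
#
# Compares molecular weight, GRAVY and predicted pI of each workflow's
# detected peptides and proteins against the in-silico tryptic digest of
# the cohort proteome (up to 2 missed cleavages, 7-35 residue window,
# proteome-wide deduplication). Rank-sum tests per workflow vs the pooled
# rest and vs the reference; BH across the family.

library(csfbench)

ch <- load_cohort("results/cohort")
out <- "results/pipeline"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
ref <- reference_distribution(ch$proteome)
obs <- lapply(ch$peptide_tables, function(tab) {
  as.list(csfbench:::physchem_table(unique(tab$sequence)))
})
tests <- compare_distributions(obs, list(mw = ref$peptides$mw,
                                         gravy = ref$peptides$gravy,
                                         pi = ref$peptides$pi))
utils::write.table(tests, file.path(out, "physchem_tests_peptides.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE, na = "")
sig <- tests[!is.na(tests$adjusted_p) & tests$adjusted_p < 0.05, ]
message(sprintf("%d of %d peptide-level contrasts significant after BH",
                nrow(sig), nrow(tests)))
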