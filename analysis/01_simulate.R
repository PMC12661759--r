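#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic study cohort.
#
# Emulates the study design: five CSF sample-preparation workflows (MStern,
# Seer, N-Gp, P20-EV, P150-EV) profiled on the same 19 patients over a
# 200-protein synthetic proteome. The generator plants (i) method-elevated
# proteins (1.5 log2 units, 10% of proteins, disjoint across workflows),
# (ii) N-glycosylation sequons with deamidation evidence and mixture-drawn
# localization probabilities, and (iii) missing-not-at-random dropout, and
# writes every downstream input: FASTA, per-workflow peptide tables, a
# deamidation site table, sample sheet, annotation files and NTA exports,
# plus ground_truth.json.
#
# Output: results/cohort/

library(csfbench)

seed <- 20260101L
cfg <- sim_config()
message(sprintf("simulating %d proteins x %d workflows x %d patients (seed %d)",
                cfg$n_proteins, length(cfg$workflows), cfg$n_patients, seed))
pr <- generate_proteome(cfg, seed = seed)
co <- generate_cohort(cfg, pr, seed = seed)
dir <- "results/cohort"
write_cohort(pr, co, dir)
n_planted <- sum(!is.na(co$truth$planted))
message(sprintf("wrote %s: %d planted elevated proteins, %d deamidation sites",
                dir, n_planted,
                if (is.null(co$site_table)) 0L else nrow(co$site_table)))
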