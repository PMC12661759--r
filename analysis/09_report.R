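#!/usr/bin/env Rscript
# Stage 9 -- consolidated end-to-end run and ground-truth scoring.
#
# Re-runs the whole chain through run_pipeline() into results/report/ (a
# single-call replication of stages 2-8) and scores the calls against
# ground_truth.json: recovery of planted method-elevated proteins and of
# planted glycosites.

library(csfbench)

ch <- load_cohort("results/cohort")
res <- run_pipeline(ch, "results/report")
truth <- jsonlite::read_json("results/cohort/ground_truth.json",
                             simplifyVector = TRUE)
planted <- unlist(truth$planted)
ev <- res$enrichment$calls[res$enrichment$calls$class == "elevated", ]
hit <- ev$protein %in% names(planted) &
  planted[ev$protein] == ev$workflow
score <- list(
  planted_elevated = length(planted),
  called_elevated = nrow(ev),
  sensitivity = sum(hit) / length(planted),
  false_discovery_proportion = sum(!hit) / max(1, nrow(ev)),
  n_glycosites = res$summary$n_glycosites,
  protein_union = res$summary$protein_union)
jsonlite::write_json(score, "results/report/ground_truth_score.json",
                     auto_unbox = TRUE, digits = NA)
message(sprintf("sensitivity %.2f, FDP %.2f over %d planted proteins",
                score$sensitivity, score$false_discovery_proportion,
                length(planted)))
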