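# csfbench

Comparative benchmarking of cerebrospinal-fluid (CSF) proteomics
sample-preparation workflows, implemented as a tested R package plus a
numbered analysis workflow.

## The problem

When the same CSF samples are prepared by different workflows — a
membrane-based digest (MStern), nanoparticle corona enrichment (Seer),
N-glycopeptide capture (N-Gp), and extracellular-vesicle pellets from
differential ultracentrifugation (P20-EV, P150-EV) — the resulting
peptide-level datasets differ in depth, reproducibility, physicochemical
bias and biological content. This package implements the analysis stages
needed to compare such workflows end to end, starting from search-engine
peptide and modification-site tables:

- **Protein-group assembly** — accessions with identical observed peptide
  sets are merged, strict subsets absorbed, shared peptides assigned to the
  group with the most distinct peptides; groups need ≥ 2 peptides and are
  quantified per sample by summing raw peptide intensities before log2.
- **N-glycosite calling** — a deamidated asparagine (PNGase-F evidence) is
  a glycosite when it lies in a canonical sequon `N-[!P]-[S/T/C]` of the
  reference sequence and its localization probability exceeds 0.8;
  glycoproteins are quantified by summing site intensities.
- **Physicochemical bias profiling** — molecular weight (monoisotopic),
  GRAVY (mean Kyte–Doolittle hydropathy) and predicted pI
  (Henderson–Hasselbalch net charge, bisection to zero) of each workflow's
  peptides and proteins, benchmarked against the in-silico tryptic digest
  of the reference proteome.
- **Detection and overlap metrics** — per-sample counts, exclusive
  UpSet-style intersections, reproducibility tiers by detection frequency,
  pairwise Spearman correlation, PCA, rank-abundance with marker panels.
- **Fraction-enrichment classification** — a protein is *unique* to a
  workflow when detected nowhere else, and *elevated* when, against every
  other workflow, the per-patient paired log2 differences give
  log2FC > 0 and BH-adjusted two-tailed signed-rank p < 0.05
  (proteins detected in ≥ 50% of samples of both workflows, ≥ 4 complete
  pairs). The *enriched* set is the union of unique and elevated.
- **Subcellular over-representation** — Fisher's exact test of each
  enriched set against the detected-anywhere background over 11
  consolidated subcellular categories, effect size as the log2
  conditional-MLE odds ratio.
- **Variance partitioning** — per protein, log2 intensity is decomposed
  under the crossed random-intercepts model
  `y ~ (1|method) + (1|patient)` fitted by EM-REML (components
  non-negative by construction), reported as percent of total variance.
- **NTA processing** — nanoparticle-tracking size distributions are
  dilution-normalized (×4 for P150-EV, ×5 for P20-EV), summarized as
  mean ± SE over technical-replicate videos, and merged on bin centers.

The statistical primitives (Wilcoxon signed-rank and rank-sum with exact
small-sample modes, BH step-up, Fisher's exact with conditional-MLE odds
ratio, mid-rank Spearman) are implemented in the package and tested against
brute-force enumeration oracles and the corresponding base-R routines.

Because raw study data cannot ship with the package, a **synthetic cohort
generator** produces the complete input surface — FASTA, per-workflow
peptide tables, deamidation site tables, sample sheet, annotation files,
NTA exports — from a crossed random-effects abundance model with planted
method-elevated proteins, planted sequons, mixture-drawn localization
probabilities and missing-not-at-random dropout, with every planted effect
recorded in a ground-truth file.

## Worked example

```r
library(csfbench)

cfg <- sim_config()                       # 200 proteins, 5 workflows, 19 patients
pr  <- generate_proteome(cfg, seed = 20260101)
co  <- generate_cohort(cfg, pr, seed = 20260101)
write_cohort(pr, co, "results/cohort")
res <- run_pipeline(load_cohort("results/cohort"), "results/report")

sum(res$enrichment$calls$class == "elevated")
res$varpart$summary
```

On this cohort the run prints stage timers to stderr and returns, among
others: 852 called glycosites across 194 glycoproteins (every planted
sequon site with localization probability > 0.8 recovered, all decoys
rejected), a protein union of 200 across workflows, 18 of 20 planted
method-elevated proteins recovered with no false calls (sensitivity 0.90,
FDP 0.00), and variance medians of roughly 29% method / 31% patient / 38%
residual — the method share here reflecting the planted effects and
detection differences, since the generator's shared method variance is
zero by default.

The same chain is available as numbered narrative drivers:

```sh
Rscript analysis/01_simulate.R    # cohort -> results/cohort/
Rscript analysis/02_assemble.R    # protein groups + matrices
Rscript analysis/03_glyco.R       # glycosites; N-Gp protein matrix
Rscript analysis/04_physchem.R    # MW / GRAVY / pI vs reference digest
Rscript analysis/05_compare.R     # overlap, tiers, correlation, PCA
Rscript analysis/06_enrich.R      # unique/elevated calls + ORA
Rscript analysis/07_varpart.R     # variance decomposition
Rscript analysis/08_nta.R         # NTA size distributions
Rscript analysis/09_report.R      # consolidated run + ground-truth score
```

## Layout

```
R/                  package code (io, stats primitives, assembly, glyco,
                    physchem, comparative stats, enrichment, varpart, nta,
                    synthetic generator, pipeline)
analysis/           numbered stage drivers (above)
scripts/            acceptance.R
tests/testthat/     oracle, property and acceptance tests
inst/extdata/       subcellular consolidation scheme; constants tables
vignettes/          methods vignette (models, parameters, design choices)
```
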