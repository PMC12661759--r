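---
title: "Benchmarking CSF sample-preparation workflows: models and design choices"
author: "csfbench"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Benchmarking CSF sample-preparation workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfbench)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the parameters that matter,
what the synthetic-data generator does and does not emulate, the numerical
choices, and the open design decisions we resolved. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The comparison problem

Five sample-preparation workflows applied to the same cerebrospinal-fluid
samples yield five peptide-level datasets over a shared patient cohort.
Every analysis in the package reduces to questions over a feature × sample
matrix of log2 intensities per workflow, with explicit missingness:
how much is detected and how reproducibly; what physicochemical bias each
workflow imposes; which proteins a workflow sees exclusively or at
elevated abundance; how detected proteins distribute over subcellular
compartments; and how much of the total variance is attributable to the
workflow versus the patient.

Detection is defined as the presence of a quantified intensity: a zero or
empty intensity field in an input table is "not detected" and is carried
as `NA`. All downstream mathematics uses log2 intensities; summation (of
peptides into protein groups, of glycosites into glycoproteins) happens on
the raw scale *before* the log, because summing log-intensities has no
physical meaning.

## Protein-group assembly

Search engines report peptides with possibly several protein accessions.
The assembly algorithm is deliberately simple, deterministic and
order-independent: (1) collect each accession's observed peptide set;
(2) merge accessions with identical sets (they are indistinguishable on
the evidence); (3) absorb any accession whose set is a strict subset of
another's (classical parsimony subsumption); (4) assign each peptide
shared between surviving groups to the group with the most distinct
peptides, breaking ties lexicographically by group id (the smallest member
accession); (5) require at least two assigned peptides per group. The
two-peptide threshold is the conventional evidence floor for confident
protein identification. Shared-peptide intensity therefore counts toward
exactly one group, which keeps per-sample group totals bounded by the
peptide totals (a conservation law the tests assert).

There is no canonical published algorithm for this step, so the rules
above are this package's definition; the tie-breaks were chosen so that
permuting input rows can never change the output.

## Glycosite calling

PNGase F converts a glycosylated asparagine to aspartate, so deamidation
evidence inside the canonical sequon N-[!P]-[S/T/C] marks a former
N-glycosite. The caller takes site tables with protein coordinates and a
search-engine localization probability, and retains a site when (i) the
probability *strictly* exceeds the threshold (default 0.8 — "exceeding"
is read literally, so 0.80 is rejected), and (ii) the position is a
sequon start in the reference protein sequence. The motif is evaluated on
the protein, not the peptide, so sequons spanning peptide C-termini are
handled correctly. Cysteine at +2 is accepted: N-X-C sequons are rare but
real. Glycoproteins keep single-site representation (no two-peptide rule)
because glycopeptide enrichment characteristically yields one peptide per
site.

## Physicochemical profiling

The in-silico reference digest cleaves after K/R, by default not before
proline (classic trypsin; the rule is a toggle because search engines
differ), with up to two missed cleavages matching common search settings,
a 7–35-residue detectability window, and proteome-wide peptide
deduplication; window and deduplication are configuration because
published reference digests are often ambiguous on both. Properties:

- **Molecular weight**: sum of monoisotopic residue masses plus one water
  (mass-spectrometry context; tables shipped in `inst/extdata/`).
- **GRAVY**: mean Kyte–Doolittle hydropathy — that scale *is* the
  definition of GRAVY.
- **pI**: the pH where the Henderson–Hasselbalch net charge over both
  termini and the D, E, C, Y, H, K, R side chains crosses zero. The
  default pKa set is Bjellqvist's (user-swappable, since no single pI
  convention dominates). Net charge is strictly decreasing in pH, so the
  zero is found by bisection on [0, 14] to 1e-4; endpoints are returned
  for peptides that are never positive (or never negative) in range.

Workflow-vs-rest and workflow-vs-reference contrasts use the two-sided
rank-sum test with BH correction across the whole (property × method ×
contrast) family; the reported shift is the difference of medians.

## Detection, overlap and tiers

A workflow's universe is the set of features detected in at least one of
its samples. Overlap is reported as exact exclusive-intersection counts
(every feature in exactly one of the 2^k−1 regions). Reproducibility
tiers bin the per-feature detection frequency into (0.9, 1], (0.5, 0.9],
(0.1, 0.5], (0, 0.1]: display conventions such as ">90% / 10–50% / <10%"
do not partition, so the fourth class is made explicit and all intervals
are half-open so each feature lands in exactly one tier. Sample
correlation is mid-rank Spearman on pairwise-complete features (pairs
sharing fewer than three features are undefined), ordered for display by
average-linkage clustering of 1−r. PCA uses complete-case features with
column centering and no imputation — the simplest defensible policy;
under heavy missingness the peptide-level PCA may be undefined, which the
pipeline records rather than hides.

## Fraction-unique, fraction-elevated, and over-representation

*Unique*: detected in exactly one workflow. *Elevated in W*: for **each**
other workflow V — not a majority, all of them — the protein must show a
positive mean per-patient paired log2 difference and a BH-adjusted
two-tailed signed-rank p below 0.05. Only proteins detected in at least
half the samples of both W and V enter a comparison, and at least four
complete patient pairs are required for the test to be defined; an
untestable comparison blocks elevation (conservative). The BH family is
each workflow pair across proteins: that matches the testing structure
and keeps families homogeneous; the alternative (one family across all
pairs) would mix very different null fractions. Zero differences are
dropped before the signed-rank test (the classic Wilcoxon convention and
the default of standard statistical software); "fold change > 0" is read
on the log2 scale as mean paired difference > 0.

The *enriched* set (unique ∪ elevated) of each workflow is tested per
subcellular category with Fisher's exact test against the background of
proteins detected in any workflow. The 11 analyzed categories and their
consolidation lists (e.g. Nucleoplasm, Nucleoli, Nuclear speckles … →
Nucleus; Midbody, Cleavage furrow … → Cell division) ship as a data file;
labels already naming a category map to themselves and unmapped labels
are dropped with a count. The odds ratio is the conditional
maximum-likelihood estimate under the noncentral hypergeometric model
(the same estimand `fisher.test` reports), reported as log2 with sign
giving direction; boundary tables yield 0/∞, which analysis tables keep
honestly — clamping is a plotting concern. Gene-set over-representation
over GMT files uses the same machinery; no ontology traversal is in
scope, identifiers must already be harmonized.

## Variance partitioning

Per protein, observations across all workflows and patients follow the
crossed random-intercepts model

y_mi = μ + a_m + b_i + ε, a ~ N(0, σ²_method), b ~ N(0, σ²_patient),

fitted by EM-REML on Henderson's mixed-model equations: variance
components stay non-negative by construction, avoiding the truncation
artifacts of moment estimators. Convergence is declared at 1e-8 on the
restricted log-likelihood with a 500-iteration cap (EM can crawl when a
component collapses toward zero; non-converged fits are flagged and
excluded from summaries). Missing cells are simply omitted observations —
mixed models tolerate unbalance and no imputation is applied. Designs
with a single method or patient, or fewer than six observations (this
package's guard), are skipped with a reason; a constant response returns
fractions (0, 0, 1) flagged degenerate. On balanced designs the estimates
coincide with Henderson's ANOVA estimators when those are non-negative,
and the tests also cross-check against an independent mixed-model
implementation (lme4). Reported fractions are invariant to affine
transforms of the data. Summaries give median, quartiles and mean per
component as percentages; medians of different components need not sum
to 100 and no such property is asserted.

When recovery of generating fractions is measured across many proteins
(tests and acceptance script), the per-protein REML *components* are
pooled before forming the ratio: with only five method levels the
per-protein fraction is a heavy-tailed ratio whose mean is biased by
Jensen's inequality even though the components themselves are unbiased.

## NTA processing

Instrument exports are a bin-center column plus one concentration column
per video. Counts are multiplied by the sample dilution factor (4 for the
P150-EV fraction, 5 for P20-EV), then summarized per bin as mean and
standard error across technical-replicate videos; SE uses the n−1 sample
standard deviation over √n (the export does not define its own SE
formula) and is missing for single-video files. Fractions are merged by
exact bin-center match (instrument grids are fixed; tolerance 1e-9 nm, no
interpolation), keeping non-shared bins with missing values.

## The synthetic cohort generator

The generator exists so every stage can be tested against known ground
truth. It emulates: a proteome with controlled tryptic-site density (K/R
at 10% of residues, i.e. a cleavage site every ~10 residues) and planted
sequons; protein log2 abundance from the crossed random-effects model
above with a baseline of N(20, 2) (typical log2 MS intensity scale);
planted method-elevated proteins (default 10% of proteins at +1.5 log2
units, disjoint across workflows); peptide intensities as the protein's
raw intensity times fixed Dirichlet(1) shares over its in-range tryptic
peptides, so protein quantification by summation is exactly recoverable
in the noise-free limit; missing-not-at-random dropout via a logistic
detection probability in log2 intensity (midpoint 14, steepness 1 —
about 27% peptide-level dropout at the default abundance scale);
deamidation sites at every true sequon plus non-sequon decoys, with
localization probabilities from a Beta(20, 1) / Beta(2, 2) mixture (high
mode for real sites, 90% weight); and NTA exports with lognormal size
modes near 120–150 nm and known dilution factors. All randomness flows
from a single mandatory seed; outputs are byte-identical across runs.

**Noise level.** The default splits a total within-protein variance of
0.5 (log2²) as (method, patient, residual) = (0, 0.5, 0.5): patient and
residual SDs of 0.5 log2 units, in the range protein-level label-free
LC-MS/MS shows for technical-plus-preparation variability, with shared
method variance held at zero so that planted effects are the *only* true
method differences. That last point matters for error accounting: a
genuine random method effect is a true method difference, so a cohort
with σ²_method > 0 is not a null for the elevated-protein classifier, and
false-discovery proportions would be uninterpretable. An earlier
provisional default used a residual SD of 0.84, which is noisier than
realistic protein-level data and starves the all-comparisons rule of
power at n = 19; the final value was fixed once as above and the recovery
experiments (sensitivity/FDP for planted effects, variance-fraction MAE)
run under it.

**What the generator does not emulate**, and hence what passing tests do
not show about real data: correlated peptide ionization efficiencies,
retention-time or charge-state effects, shared peptides between homologous
proteins (random sequences essentially never collide), batch effects or
acquisition drift, non-Gaussian abundance tails, and any relationship
between subcellular category and abundance unless the per-workflow
capture-probability matrix is set explicitly. Recovery results on this
generator demonstrate correctness of the inferential machinery under the
stated model, not performance on real cohorts.

## Problem sizes and determinism

The test suite and acceptance script use the study-scale cohort —
200 proteins × 5 workflows × 19 patients — for end-to-end runs;
variance-fraction recovery uses 20 replicate balanced datasets, the
planted-effect experiment 3 replicate cohorts, and the null
BH-control check 50 replicate cohorts at the protein level; generator
calibration is checked at 2000 proteins × 50 patients on the abundance
array alone. These sizes were chosen so each experiment's Monte-Carlo
error is small against the quantity it checks while the whole suite stays
comfortably interactive. Exact-mode statistical tests switch to
approximations at n = 12 (or under ties), recorded per result in a
`method_note`; all pipelines are deterministic given the seed, which the
byte-identity test asserts file by file.

## Known limitations

- The grouping algorithm is one defensible parsimony scheme among
  several; razor-peptide multi-assignment and isoform inference are out
  of scope.
- No normalization is applied between samples after summation; workflows
  with global intensity offsets will show them (the paired design absorbs
  patient-level offsets but not sample-specific ones).
- ORA treats categories independently; no hierarchy or correlation
  between compartments is modeled.
- The EM-REML fitter handles exactly two crossed random factors and no
  fixed-effect covariates.
- p-values from the normal-approximation Wilcoxon paths are approximate
  for heavily tied data; the exact modes cover only small samples.
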