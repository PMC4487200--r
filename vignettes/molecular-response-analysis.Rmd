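---
title: "Molecular response analysis in intrinsic-subset stratified SSc trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular response analysis in intrinsic-subset stratified SSc trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intrinsicSSc)
```

## The analysis problem

Diffuse cutaneous systemic sclerosis (dcSSc) trials are small: ten patients
randomized 2:1, a subset of them with paired skin biopsies at baseline and
week 24, and the modified Rodnan skin score (mRSS, an integer 0–51) measured
at eight scheduled visits (days 1, 15, 29, 57, 85, 113, 141, 169). At this
scale the clinical signal (does the drug lower mRSS?) and the molecular
signal (does treatment erase an inflammatory gene-expression program in
responders?) have to support each other. `intrinsicSSc` implements both
layers and the join between them: per patient, the improver flag, the
baseline intrinsic subset call, and the signature trajectory.

This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## Expression preprocessing

Two-colour array data arrive as a probes × samples matrix of log2 ratios
with missing entries. The chain is: *filter* → *impute* → *median-center* →
*collapse*.

- **Missingness filter** (`filterProbesByMissingness`): a probe is removed
  when its missing fraction is *strictly greater* than `maxMissingFrac`
  (default 0.2). A probe at exactly 20 % is retained — the rule removes
  "> 20 %", not "≥ 20 %".
- **KNN imputation** (`imputeMissingKnn`): each missing cell is the
  unweighted mean, over the `k = 10` nearest rows, of that column's value.
  Row distance is the mean squared difference over mutually observed
  columns (scale-free in the number of shared columns); rows missing the
  target column are not eligible neighbours. If fewer than k eligible
  neighbours exist, all are used. A column observed nowhere is an error
  rather than a silent zero.
- **Median centering** (`medianCenterRows`): per-row median subtracted; the
  even-length median is the midpoint, so `c(4, 8)` centers to `c(-2, 2)`.
  The operation is idempotent and shift-invariant.
- **Collapse** (`collapseProbesToGenes`): default rule `max` — the probe
  with the highest mean expression across samples represents the gene as a
  whole row (never a per-cell maximum, which would chimerize probes);
  `mean` and `median` aggregate per cell instead. Unmapped probes are
  dropped and counted.

Centering defaults to the probe level before collapsing, matching the order
used for the intrinsic analysis; `centerAfterCollapse = TRUE` gives the
alternative order, and the run report records which was used.

## Intrinsic subset assignment

A labelled reference cohort defines the subsets. The centroid of subset *s*
is the arithmetic mean expression of each intrinsic gene over the reference
samples labelled *s* (`buildSubsetCentroids`); the `limited` subset is
excluded by default because diffuse-cutaneous trial cohorts contain no such
patients. Intrinsic genes absent from the study platform are dropped with a
count — on real platforms roughly four of five reference genes survive the
intersection, and the classifier must tolerate that loss.

A sample is assigned (`assignIntrinsicSubset`) by Spearman correlation
against each centroid over the shared genes: midranks for ties, and the
two-sided p-value from exact enumeration of all permutations when n ≤ 9 and
the data are untied, else from the t-approximation
t = ρ√((n − 2)/(1 − ρ²)). The call is the subset with the highest ρ. Two
edge rules are explicit:

- **ρ vs p**: with equal gene overlap per subset, the lowest two-sided p
  does not always accompany the highest ρ (a strong *negative* correlation
  also has small p); that situation is not a genuine conflict and is
  resolved by ρ. A warning is recorded only when the per-subset gene
  overlaps differ, which is the one situation where the dual criterion can
  genuinely split.
- **Ties in ρ** are broken by smaller p, then alphabetically, with a
  warning; they occur only in pathological inputs.

Because the statistic is rank-based, calls are invariant under any strictly
monotone transform of the sample vector — a property the test suite checks
directly. Healthy controls take part in the clustering display and in the
centering distribution but receive no subset call.

Signature scores (`scoreSignature`) are per-sample means of centered
expression over the genes of a set that are present in the matrix; deltas
(`signatureDelta`) pair baseline and post scores through the patient table,
and their significance in improvers uses a paired t-test
(`compareSignatureGroups`).

Hierarchical clustering (`hierarchicalCluster`) uses average linkage on
1 − Pearson correlation (uncentered-correlation option available for
fidelity to the classic clustering tools); a zero-variance item gets
correlation 0 to everything with a warning rather than an error. Dendrogram
exports are Newick (`writeDendrogramNewick`, via `ape`) and CDT/GTR-style
tables (`writeCdt`).

## Marker selection and enrichment

`twoClassMarkerSelection` is a per-gene Student t: paired designs test the
per-pair differences, unpaired designs use the pooled-variance two-sample
t. At n ≤ 7 per class no multiple-testing correction is applied for the
significance call — uncorrected p < 0.05 is the operative rule at this
cohort size, and BH q-values are reported alongside for information.
Zero-variance genes are flagged `degenerate` (p = 1 when means agree, the
smallest representable p when a nonzero difference has zero variance) and
never dropped silently. A permutation p (label permutation or sign flips)
is available via `nPerm`.

`gsea` ranks genes by signal-to-noise (with the classic variance floor
sd ≥ max(0.2·|mean|, 0.2)) and computes the weighted Kolmogorov–Smirnov
running sum: hits increment by |metric|^weight normalized over the set,
misses decrement by 1/(N − N_h); the enrichment score is the signed
extremum. The null is built from **gene-set permutation** — random sets of
matched size — because sample permutation is unsound with three or four
samples per class; sample permutation remains available behind
`permType = "sample"`. NES divides ES by the mean |null ES| of the same
sign; FDR q follows the pooled positive/negative-tail procedure with
monotonicity enforced within each sign pool, and FDR < 10 % is the default
significance threshold. Set-size filters default to 15–500 but are fully
configurable, since signature sets of 19 or 62 genes must be scorable.
"Core enrichment" is the set members at or before the extremum on the ES's
sign side.

`ssgseaProject` is deterministic: per sample, genes are ordered by
decreasing expression (ties keep input order), and the score integrates the
difference between the weighted ECDF of set genes (weight rank^α,
α = 0.75) and the unweighted ECDF of the rest. A constant sample carries no
ranking information; its scores are defined as 0 with a warning.
`overrepresentationTest` is the self-contained annotation substitute: a
one-sided hypergeometric tail with BH adjustment, significant at q < 5 %.

## Clinical statistics

- **LOCF** (`applyLocf`): missing scheduled visits take the most recent
  observed value; filled cells are flagged. A patient withdrawing after the
  week-16 visit contributes that value to the final-visit analysis.
- **Improver** (`classifyImprover`): relative change
  (baseline − final)/baseline ≥ 0.30, boundary inclusive (a 30-to-21
  trajectory is an improver), evaluated at the day-169 value post-LOCF.
- **Summary-statistic t** (`summaryTwoSampleT`): pooled variance by
  default — with published per-arm mean ± SD rows the pooled form
  reproduces the printed comparisons, where Welch does not — with Welch
  behind `pooled = FALSE`.
- **Fisher's exact test** (`fisherExact2x2`): two-sided p by the
  probability-mass rule (all tables with the observed margins whose
  probability does not exceed the observed table's, within relative
  tolerance 1e-7). Zero-margin tables return p = 1 with a flag.
- **Wilcoxon signed rank** (`wilcoxonSignedRank`): zeros dropped (the
  classical policy), midranks for tied magnitudes, and an exact two-sided p
  for n ≤ 25 computed by dynamic programming over doubled ranks — the
  standard library routine abandons exactness under ties, so the exact
  tied-rank null is implemented here. Above n = 25 the normal approximation
  applies with tie and continuity corrections.
- **Mixed model** (`fitMrssMixedModel`):
  mRSS ~ duration + drug + visit (+ visit × drug) with a patient random
  intercept, fitted by REML through `lme4`. Confidence intervals and
  p-values use a t reference with residual degrees of freedom
  n_obs − p_fixed − (n_patients − 1), the classic within-subject
  convention; the method string is recorded in the fit object. A boundary
  (zero) intercept variance is reported as such, in which case the fixed
  effects coincide with OLS on a balanced design. Satterthwaite df were
  deliberately left out to keep the df convention explicit and auditable.

## The synthetic-data generator

`simulationConfig` fixes the study conditions once:

| parameter | default | meaning |
|---|---|---|
| `nGenes` | 2000 | simulated genes |
| `nSignatureGenes` | 100 | signature genes per subset |
| `effectSize` | 2.0 | log2 shift of a subset's signature in its samples |
| `noiseSd` | 0.5 | Gaussian noise sd (log-ratio scale) |
| `nReferencePerSubset` | 30 | reference samples per subset |
| `nPatientsPerArm` | 7 / 3 | randomized patients (abatacept / placebo) |
| `nBiopsiedPerArm` | 6 / 2 | patients with paired biopsies |
| `nHealthy` | 4 | healthy-control samples |
| `signatureDecay` | 1.5 | post-treatment signature loss in treated improvers |
| `nonImproverDrift` | 0.3 | mild post-treatment signature gain otherwise |
| `drugEffect` | −9.8 | mRSS drug effect |
| `durationSlope` | −0.9 | mRSS per disease-duration year |
| `interceptSd`, `residualSd` | 6, 3 | mRSS variance components |
| `durationMean/Sd` | 2.4 ± 1.6 / 8.8 ± 3.8 | disease duration per arm |
| `missingnessRate` | 0.02 | MCAR rate applied when files are emitted |

The effect size, noise, patient counts, duration distributions and mRSS
model parameters mirror the published trial design and its summary tables;
where no value was published (signature size, decay, drift, missingness
rate) the defaults are one-time choices at the scale typical of two-colour
skin-biopsy data. The mRSS intercept (36) puts simulated baselines in the
low-to-mid 20s for the treated arm and high 20s for placebo — close to, but
not exactly, the published medians, because a single additive model cannot
match both arms' baselines and the adjusted treatment effect
simultaneously; the recovery simulations only require the generating model
to equal the fitted model.

Improver flags derive from the generated trajectories (relative change at
visit 8; a zero-baseline trajectory cannot improve by a relative
criterion). With `forceImproverFraction = TRUE` the configured fractions
(5/7 and 1/3) are imposed instead, and the trajectories are rewritten as
linear ramps to a ~40 % (improver) or ~10 % (non-improver) final decrease
so the flags stay derivable from the data; forced cohorts are therefore
*not* draws from the mixed model and are not used in the mixed-model
recovery simulations. Treated improvers have their own subset's signature
decayed toward background post-treatment; everyone else drifts mildly
upward, matching the observed pattern that non-improvers and placebo
patients become more, not less, inflammatory.

What the generator does **not** emulate: probe-level structure (it draws
genes directly), dye and batch effects, spatial artifacts, correlated gene
modules beyond the signature blocks, dropout-censored visit patterns, and
informative missingness (the MCAR flag is the only missingness mechanism).
Passing recovery tests on these cohorts therefore demonstrates the
correctness of the estimators under their own assumptions, not robustness
to real-array pathology.

## Numerical choices and degenerate inputs

- Exact Spearman p only for n ≤ 9 *and* untied data; ties always use the
  t-approximation (documented rather than mixing enumeration conventions).
- Missingness-threshold and improver-threshold comparisons carry a 1e-12
  tolerance so that 3/10 and 0.3 compare as intended in floating point.
- KNN neighbour ties are broken by row order; ssGSEA expression ties keep
  input order; both make reruns bit-identical.
- Degenerate statistics are flagged, not hidden: zero-variance genes,
  zero-margin tables, all-zero difference vectors, constant samples and
  boundary variance estimates each have a defined, tested behaviour.

## Problem sizes used in validation

The test-suite and acceptance-script simulations use 1000-gene cohorts with
200 probe samples for subset recovery, 1,000 null genes for type-I-error
calibration, 200 replicates of 30 patients × 8 visits for mixed-model
recovery and CI coverage, and 100–200 replicates of the 7 + 3 trial design
for signature-decay power — sizes at which every Monte-Carlo margin in the
checks is several binomial standard errors wide.

## Known limitations

- The nearest-centroid classifier reports no "unclassifiable" category; a
  sample weakly correlated with all centroids still receives the argmax
  call (the margin and p-values are the tools for flagging weak calls).
- Gene-set permutation nulls answer a different question than sample
  permutation (set coherence vs class association); with adequate sample
  sizes the sample-permutation flag should be preferred.
- The residual-df convention for mixed-model inference is mildly liberal
  with ten patients (the acceptance simulations measure ~91–93 % coverage
  for nominal 95 % intervals at 30 patients).
- The exact Wilcoxon path is O(n · Σranks) in time and memory via the DP
  table; at the default `exactMax = 25` this is negligible.
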