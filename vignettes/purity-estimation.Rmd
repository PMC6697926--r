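---
title: "Reference-free tumor purity from methylation arrays: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free tumor purity from methylation arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

DNA extracted from a bulk tumor sample is a mixture: neoplastic cells,
infiltrating immune cells, vessels, fibroblasts. On a 450K-style
methylation array this admixture shows up as *intermediate* beta values at
CpGs where tumor and stroma disagree — a probe that is methylated in the
tumor compartment (beta near 1) and unmethylated in the stromal compartment
(beta near 0) reads out approximately

$$\beta_{ij} \approx p_j\, t_i + (1 - p_j)\, s_i,$$

where $p_j$ is the tumor-cell fraction (purity) of sample $j$ and $t_i,
s_i$ are the compartment reference betas of probe $i$. Purity is therefore
a latent variable that confounds clustering, classification and
differential methylation, and most existing estimators need matched normal
tissue or restrict to cohorts where a reference panel exists.

`purityforest` estimates $p_j$ directly from the beta matrix, without
matched normals, by regressing gold-standard purity labels (from a
copy-number method such as ABSOLUTE, or an expression method such as
ESTIMATE) on the beta values of probes selected for *multimodality* — and
by shipping a synthetic admixture generator so every claim the package
makes about itself is testable end to end.

## Probe screening: the dip statistic

Across a cohort whose samples span a range of purities, an informative
probe's betas split into clusters (entities with different typical purity,
methylated vs unmethylated tumor states), while a purity-blind probe is
unimodal noise around its reference value. Hartigan's dip statistic
measures exactly this:

$$D_n = \inf_{G\ \text{unimodal}} \sup_x |F_n(x) - G(x)|,$$

the smallest sup-norm distance between the empirical CDF $F_n$ and any
unimodal CDF (convex below its mode, concave above it, an atom allowed at
the mode). `dip_statistic()` computes it exactly: ties are collapsed into
blocks, and for every candidate mode placement the smallest attainable
distance on the convex side is half the largest gap between the ECDF's
upper step corners and the greatest convex minorant of its lower corners
(mirrored with the least concave majorant on the concave side); the dip is
the minimum over placements, floored at $1/(2n)$, the ECDF jump at a data
point. Useful anchors, all tested: $D_2(\{0,1\}) = 0.25$; $n$ equally
spaced points attain the floor $1/(2n)$; a balanced two-point mass attains
the universal cap $0.25$; the statistic is invariant under positive affine
transforms and reflection. The implementation is verified against two
independent brute-force oracles (a grid search over mode placements with
chord-searched minorants, and a feasibility bisection on the distance) to
$10^{-9}$ on hundreds of random samples.

Design choices here:

* **Ties are retained.** Beta values quantize; dropping duplicates would
  inflate the dip of tied unimodal probes.
* **A constant probe returns the floor** $1/(2n)$ rather than an error, so
  it ranks last but stays comparable.
* **`min_samples = 10`** (default): the dip of tiny samples is pinned near
  its bounds and carries no ranking information; probes with fewer
  non-missing values are excluded and reported.
* **Ranking ties break by probe id**, so screening is bit-reproducible.
* **Screening runs on the training partition only.** The held-out samples
  never influence probe selection (see *Leakage* below).
* `rank_probes_by_sd()` provides the variance-screening comparator; on the
  synthetic cohorts the dip-screened top 20% yields an out-of-bag error no
  worse than a 5% screen, matching the motivation for the 20% default.

`select_top_fraction()` keeps `ceiling(fraction * n)` probes — the ceiling
never returns an empty set for a positive fraction.

## The two-step forest

1. **Partition.** `partition_samples()` draws a stratified 70/30
   train/test split: stratified on the entity label when present (so every
   entity is proportionally represented), else on outcome quintile bins.
   Per stratum the realized training share is within one sample of
   nominal; a singleton stratum falls back to a pooled split with a
   warning flag.
2. **Screening.** Top 20% of training-complete probes by dip (default).
3. **First forest.** A 500-tree regression forest of purity on the
   screened probes, used only for its impurity-decrease (node-variance
   reduction) importance ranking; permutation importance is available by
   flag.
4. **Candidate sweep.** For fractions 0.1%, 1%, 5%, 10% *of the screened
   set*, a forest on the top probes by importance, scored by out-of-bag
   mean squared error — each training sample predicted only by trees whose
   bootstrap excluded it. The chosen candidate minimizes OOB error, ties
   going to the smallest probe count.
5. **Final forest.** Refit on the chosen probe set; the model archive
   stores the probe set, the ensemble, the whole sweep record, the
   training-set probe medians, the partition and the config.

Two denominators deserve a note. The candidate fractions are taken of the
*screened* set, not the full array: on a full 450K array (428,000 usable
probes) screened to its top 20% (85,600 probes), the 1% candidate is the
canonical 856-probe model size (`candidate_probe_counts(85600, 0.01)`);
fractions of the full array could not produce that size from these
percentages. And 500 trees are used at *every* stage — the forest engine
(`ranger`, single-threaded, seeded) makes all stages deterministic given
the config seed, from which one sub-seed per stage is derived.

**Missing values.** Forests need a complete design, so probes with any
missing value across the training samples are dropped before screening.
At prediction time the opposite policy applies: model probes absent from
the new matrix (or missing cells) are imputed with the training-set
median, which is robust on $[0,1]$, and the per-sample imputed fraction is
reported so the user can judge how much of the signature was actually
measured.

**Prediction range.** Predictions are the mean of tree outputs, truncated
into $[0,1]$: averaging in-range leaf values cannot leave the range, but
imputation edge cases are guarded, and purity is a proportion.

**Leakage.** Probe selection must not see the held-out data. Re-running
the pipeline on the training samples alone would re-split them (the
partition contract forces a 70/30 split of whatever it is given), so
`train_purity_model()` accepts an explicit `partition`; holding the
original assignment fixed while deleting every test sample reproduces the
screening, the importance ranking and the final probe set bit for bit —
asserted in the test suite.

## LUMP, evaluation and annotation machinery

* `lump_score()`: the immune-hypomethylation purity proxy — the mean beta
  over a panel of CpGs unmethylated in leukocytes, divided by 0.85 and
  capped at 1. The published 44-probe panel is not redistributed here; the
  panel is a user-supplied file, and the simulator emits a synthetic
  placeholder panel (tumor-methylated, stroma-unmethylated planted probes)
  for tests. Both the scaled (default) and raw means are exposed.
* `evaluate_predictions()`: Pearson r, MSE and median absolute difference
  on the sample intersection; zero-variance inputs flag r as undefined
  while MSE is still returned.
* `purity_quantiles_by_group()`: per-entity quantiles with linear
  interpolation between order statistics (R's type 7) — recorded so the
  cut-off tables are reproducible.
* `region_fractions()` / `tsg_overlap_fraction()`: probe-set
  characterization against a manifest-style annotation. *Promoter* is
  operationalized as TSS200 ∪ TSS1500 (whether 5'UTR/1stExon belong to a
  promoter is a convention; this one is the narrow manifest reading, and
  it is recorded rather than configurable). Categories overlap, so
  fractions need not sum to 1. Gene matching is exact and case-sensitive
  after whitespace trimming; a probe matching several listed
  tumor-suppressor genes counts once in the fraction but contributes all
  symbols to the matched list.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the reference test bed: 3 entities × 100
samples × 20,000 probes, 600 planted informative probes.

* **Compartments.** A shared stromal methylome and per-entity tumor
  methylomes. Informative probes take opposed references (high law on
  $[0.85, 0.95]$ vs low law on $[0.05, 0.15]$, direction random per
  probe), so tumor and stroma disagree by 0.7–0.9. Non-informative probes
  share one reference drawn from a U-shaped Beta(0.5, 0.5), the typical
  across-probe landscape of a 450K array; 500 of them receive
  entity-specific logit-scale perturbations (SD 1) of the tumor profile,
  giving the cohort entity structure that is *not* purity signal.
* **Purity.** Per-entity Beta laws with means 0.90, 0.60 and 0.30
  (Beta(45,5), Beta(30,20), Beta(15,35)) — the span of real copy-number
  purity means across entities, from near-pure tumors to heavily
  infiltrated ones. The entity separation is what makes the planted
  probes multimodal across the cohort: with a single shared purity law the
  mixture $s_i + p(t_i - s_i)$ is an affine image of a unimodal law, the
  dip cannot distinguish it from noise probes (the dip is affine
  invariant), and screening collapses — this was measured, not assumed.
  The price is a within-entity spread (SD ≈ 0.04–0.08) tighter than real
  cohorts; see *Limitations*.
* **Noise.** Logit-scale Gaussian noise (SD 0.3) with boundary clipping at
  $10^{-6}$: preserves $[0,1]$ and mimics the heteroscedasticity of beta
  values (tight near 0 and 1, broad mid-scale). With the noise off, every
  simulated beta is the exact convex combination of its references —
  asserted in the tests.
* **Labels.** Two gold-standard sets derived from the true purity with
  independent logit noise (SD 0.2, keeping cor(label, truth) ≥ 0.95 so the
  regression is well-posed); the ESTIMATE-like set adds a +0.25 logit
  offset, reproducing the systematic ESTIMATE-above-ABSOLUTE difference
  (≈ +0.04 on the purity scale at these purities). Training one model per
  label set propagates the offset into the predictions, and the tests
  assert the resulting ordering on the shared test set.
* **Reproducibility.** One master seed feeds a derived seed per stage
  (profiles / purities / noise / masking / labels), so stages are
  independently reproducible and `make_fixture_suite()` is byte-stable.

Not emulated: Infinium I/II chemistry and probe-type effects, copy-number
aberrations, batch effects, realistic cell-type deconvolution structure
(the stroma is a single compartment), and realistic within-entity purity
spread. Passing tests on this generator therefore demonstrate that the
pipeline recovers admixture signal of the stated form at desk scale — they
do not certify accuracy on any real cohort, where label noise, entity
overlap and probe chemistry are all less favorable.

## Problem sizes and numerical conventions

The validation suite trains on the reference cohort (300 × 20,000, seeds
1–3); unit tests use a 120 × 2,000 miniature of the same design. These
sizes were chosen as the smallest at which all of the pipeline's
qualitative behavior (screening recovery, OOB selection, offset
propagation) is stable across seeds. Other conventions: beta matrices are
TSV with probes as rows and `NA` as the missing token, round-tripping
bit-identically (shortest-roundtrip doubles); values within $10^{-9}$
outside $[0,1]$ can be clamped as floating-point dust in lenient read
mode, anything worse aborts; model archives embed a format-version string
and refuse to load across versions; all tie-breaks everywhere are
deterministic (statistic descending, then probe id).

## Limitations

* The within-entity purity spread is tighter than in real cohorts; with
  realistic spread the planted-probe recovery of dip screening degrades
  gracefully (more overlap between the dip distributions) and the 95%
  desk-scale recovery should not be quoted as a field expectation.
* The dip scan is exact but quadratic per probe in the worst case
  (amortized near-linear on typical shapes); cohorts of thousands of
  samples will feel it.
* Gold-standard biases are inherited by construction: a model trained on
  offset labels reproduces the offset. This is a feature for
  extrapolation and a caveat for interpretation — purity values should be
  compared within an entity, against the per-entity quantile tables,
  rather than read as absolute cell fractions.
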