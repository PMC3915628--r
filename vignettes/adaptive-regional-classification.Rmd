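---
title: "Adaptive regional pattern classification of tissue-density maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive regional pattern classification of tissue-density maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compareMRI)
```

# The problem

Structural MRI studies of mood disorders ask whether a multivariate pattern
of regional brain-tissue differences can classify individual patients —
for example, first-episode psychotic bipolar-I disorder (BD) versus
psychotic major depression (MDD) versus healthy controls (HC). The analysis
chain this package implements has four stages:

1. **Mass-preserving tissue-density maps.** After segmentation and spatial
   normalization to a template, each subject's grey matter (GM), white
   matter (WM) and ventricular CSF are represented as density maps in which
   the value at a voxel is the *amount* of tissue mapped there, so that a
   regional sum is a volume. Maps are corrected for total brain volume
   (TBV, brain tissue plus CSF) and smoothed with an 8 mm Gaussian kernel.
2. **Adaptive regional feature extraction.** Voxelwise Pearson correlation
   `r` between density and 0/1 group membership ranks voxels by
   discriminative power `|r|`; a watershed transform groups above-floor
   voxels into catchment basins around the `|r|` peaks; from each basin's
   peak a region is grown greedily, adding the 26-neighbour that maximizes
   the `|r|` of the summed regional volume as long as inclusion does not
   decrease it. Each grown element contributes one feature: the per-subject
   sum of density over its voxels. An intraclass correlation, ICC(1,1),
   over the element's seed neighbourhood measures spatial consistency and
   breaks ranking ties.
3. **Feature selection and classification.** Recursive feature elimination
   on squared linear-SVM weights ranks the candidate elements; the retained
   subset size maximizes internal cross-validated accuracy computed on
   training subjects only. A Gaussian radial-basis-function SVM is trained
   on the standardized selected features and yields a signed decision score
   (positive = patient-like).
4. **Nested leave-one-out evaluation.** Each subject is held out once;
   *all* of stages 2–3 are re-run on the remaining subjects. Pooled
   held-out scores, standardized to Z scores, feed the ROC curve, the AUC
   (the probability a random patient outscores a random control, ties
   counted half), accuracy and the threshold-dependent metrics
   (sensitivity, specificity, PPV, NPV) at the accuracy-maximizing
   threshold. A 0–1 feature-frequency map records in what fraction of folds
   each voxel belonged to a selected element.

Because the original scans are not public, the package ships a seeded
synthetic-cohort generator and reproduces the published *printed*
statistics (the contingency-derived diagnostic table and the cohort-table
tests) exactly, while the behaviour of the full pipeline is established by
property-based simulation.

# The synthetic cohorts

`generate_cohort()` emulates the study data, not real anatomy:

* **Demographics.** Age is truncated normal on the 18–50 inclusion window
  with the published group means and SDs (BD 27.09 ± 8.87, MDD
  29.05 ± 8.34; the HC profile pools the two matched control subsamples);
  gender, handedness and scanner are Bernoulli draws with the published
  proportions (e.g. 39.1% male in BD, 100% right-handed in BD, 84.2% in
  MDD). The scanner indicator defaults to a 55/45 split, matching the
  roughly 52–66% scanner-1 fractions of the three comparisons.
* **Maps.** A fixed smooth radial phantom (a GM shell, a WM core, an outer
  CSF rim and a central ventricular sphere) plus i.i.d. per-voxel Gaussian
  noise (`noise_sd`, default 1 density unit) inside the brain mask.
  Negative values are clamped at zero; the phantom amplitude (10) keeps
  clamping negligible. Group differences are planted as additive mean
  shifts of `effect_size * noise_sd` inside a sphere, before smoothing —
  the simplest model of a focal volumetric abnormality.
* **Processing.** Each subject is TBV-normalized (reference 1, so maps are
  fractions of brain volume) and then smoothed (default 8 mm FWHM on 2 mm
  voxels, σ = 1.699 voxels). The order — normalize, then smooth — is a
  choice the source pipeline leaves open; both orders commute with the
  correlation-based downstream statistics, and the flag
  `tbv_normalize` plus `smoothing_fwhm = 0` let either step be disabled.
* **Default problem size.** 16³ voxel grids with 20 subjects per group for
  simulation studies. This is a deliberately scaled-down template space:
  large enough for the watershed to produce tens of basins per compartment
  (candidate counts near the published 53–99 features) and for the
  no-leakage and signal-recovery properties to be measured across dozens of
  cohorts, small enough that a full nested LOOCV takes seconds.

What the phantom does **not** emulate: anatomical boundaries and folding,
spatially correlated physiological noise, scanner-specific intensity
artifacts, registration error (deformations are exact inputs here),
medication and comorbidity effects. Passing tests therefore demonstrate the
*statistical correctness* of the pipeline — chance-level behaviour without
signal, recovery of planted signal, exact metric arithmetic — not that any
particular clinical discrimination is achievable on real data. That
matters: the study this design follows found near-chance real-data
performance, and the decisive property of a trustworthy implementation is
precisely that it does **not** manufacture accuracy from noise.

`match_controls()` implements the hierarchical matched-control selection:
candidates are scored per case at three levels (gender + age within 2
years + handedness, then gender + age, then gender alone; wrong-gender
candidates are never taken), and cases draw their best remaining candidate
round-robin so that as many controls as possible are accumulated up to
`max_controls`. Ties break by smallest absolute age difference, then lowest
pool index — deterministic and auditable. The source study does not state
how many controls per case were sought ("as many as possible"), so the cap
is an explicit parameter rather than a guess.

# Mass preservation as the defining semantic

The map constructors treat *mass conservation* as the contract:

* `mass_preserving_warp()` moves each source voxel's tissue amount to its
  displaced position and splits it over the 8 surrounding voxels by
  trilinear weights (positions clamped to the grid). Total mass is
  conserved exactly by construction; compression raises density, expansion
  lowers it. This forward-splatting construction was chosen over
  interpolating pullback precisely because pullback does not conserve mass.
* `smooth_map()` uses separable Gaussian kernels that are renormalized per
  *source* voxel at the volume edges (column-normalized convolution
  matrices), so smoothing redistributes mass without creating or losing it.
* `normalize_tbv()` rescales all compartments by one common factor to a
  reference TBV of 1.0. Any positive reference is equivalent (the published
  pipeline names no constant); 1.0 makes maps unit-free fractions.
  The operation is idempotent and commutes with global rescaling of the
  input — properties the test suite checks directly.
* `isolate_ventricles()` intersects a CSF map with a template ventricular
  mask. The original automated isolation algorithm is unpublished; mask
  intersection implements its observable contract (ventricular CSF in,
  everything else zeroed).

# Numerical and design choices in the classifier

* **Discriminative power is `|r|`.** Group membership is coded 0/1 and
  Pearson correlation is used both voxelwise and for regional features;
  constant voxels score 0 by convention.
* **Watershed floor.** Voxels with `|r| < 0.1` are background. The source
  method names no floor; 0.1 keeps candidate counts at the published scale
  on these grids and is exposed in `compare_config()`. Candidates are
  pooled across GM, WM and ventricular maps (the alternative — one
  classifier per compartment — is noted as an open question in the source;
  pooling is the package default) and capped at `max_candidates = 60` in
  decreasing order of seed power.
* **Region growing accepts ties.** Growth stops when the best neighbour
  would *decrease* regional power ("will not decrease" is the stated rule);
  a plateau of uniform effect therefore grows to its basin. Growth is
  bounded by the watershed basin and a size cap (32 voxels by default) as
  dimensionality control.
* **"SVM criteria" selection.** The original description does not pin down
  the criterion; this implementation uses the classic recursive feature
  elimination on squared linear-SVM weights (dropping 25% of remaining
  features per step), with the retained subset size chosen by deterministic
  stratified 5-fold cross-validation *inside the training set*, smaller
  subsets winning ties. Everything — fold assignment, tie-breaks,
  elimination order — is a pure function of the data, so identical inputs
  give identical selections.
* **SVM defaults.** Gaussian RBF kernel with `gamma = 1/n_features` on
  standardized features and `cost = 1` (the source states no
  hyperparameters; these are the field's conventional defaults and are
  recorded in the configuration). Features are standardized with statistics
  frozen from the training fold. Class weights are balanced (inverse class
  frequency) by default: leave-one-out makes the held-out subject's class
  one subject smaller in training, and an unweighted SVM then acquires a
  systematic majority-class vote that pushes null-data accuracy below
  chance; balancing removes this artifact of the resampling scheme, not of
  the data.
* **Scores.** `classify()` returns the signed RBF decision value; the LOOCV
  harness pools the held-out scores and standardizes them to mean 0,
  SD 1 — the "Z score" convention under which the ROC is drawn. ROC points
  are one per distinct threshold; AUC counts tied pairs as half-concordant,
  which makes the trapezoidal staircase integral and the rank-statistic
  definition agree to machine precision (asserted in the tests).
  `best_threshold()` maximizes accuracy, breaking ties toward higher
  specificity.

# Table statistics and the inverse reconstruction

`chi_square_2x2()` is the Pearson statistic without continuity correction —
validated because it alone reproduces the four published chi-square values
(1.59, 5.43, 4.27, 3.91) from the printed counts; Yates correction sits
behind a flag. `two_sample_t_summary()` is the pooled-variance t computed
from printed means/SDs (df = 40 for the published age row; the printed
means are rounded, so |t| is asserted to the interval 0.72–0.75 rather than
a point). `mann_whitney_test()` wraps the rank-sum test with exact p for
small untied samples.

`reconstruct_confusion()` inverts the printed diagnostic table: it searches
all integer (tp, tn) pairs whose sensitivity/specificity percentages match
the printed values within a tolerance. At the pure-rounding tolerance of
0.05 percentage points, two of the three published rows reconstruct
uniquely; the third (BD vs MDD) needs 0.1 because its printed specificity
52.1 is a truncation of 52.17. Two further published cells are truncations
rather than roundings (NPV 66.6 vs computed 66.67; the MDD scanner
chi-square 0.92 vs computed 0.925): the package rounds half-away-from-zero
and documents the discrepancy instead of mimicking truncation. The
BD-vs-MDD row is only consistent with *MDD* as the positive class, which is
how the packaged reference table encodes it.

# Known limitations

* The phantom's noise is spatially white before smoothing; real
  morphometric noise has anatomy-locked structure, so real candidate counts
  and selection stability will differ.
* The greedy region growing is order-dependent by design (it follows the
  stated accretion rule); it is deterministic but not globally optimal.
* Watershed behaviour on exact plateaus follows the underlying flooding
  implementation's tie handling; plateaus are measure-zero for continuous
  data but do occur in constructed examples.
* `classify()` scores are comparable only within one evaluated set after Z
  standardization; absolute decision values across separately trained
  models are not calibrated probabilities.
* The real-data discrimination results of the source study (AUC 0.61, 0.44,
  0.52) require the original scans and are out of scope; nothing in this
  package estimates them.

# Reproducing the printed numbers

```{r table2}
t2 <- table2_printed()
for (i in seq_len(nrow(t2))) {
  cm <- reconstruct_confusion(t2$n_pos[i], t2$n_neg[i],
                              t2$sensitivity[i], t2$specificity[i],
                              t2$tolerance_pct[i])
  print(diagnostic_metrics(cm))
}
cohort_table_stats()
```

A full simulation experiment, end to end:

```{r pipeline, eval = FALSE}
spec <- cohort_spec(n_per_group = c(BD = 20, HC = 20),
                    effects = list(effect_spec(c(8, 8, 8), radius = 3,
                                               effect_size = 2.5, "GM")),
                    seed = 11)
res <- run_comparison(generate_cohort(spec), "BD", "HC")
res$report
```
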