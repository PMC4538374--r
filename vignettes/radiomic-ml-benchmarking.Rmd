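---
title: "Benchmarking feature selection and classification for radiomic survival biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking feature selection and classification for radiomic survival biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radbench)
```

## The problem

A radiomic biomarker pipeline has three experimental knobs: the filter
method that ranks features, the classifier trained on the selected subset,
and the subset size. radbench evaluates all three jointly for two-year
survival prediction on a training/validation cohort pair, scoring each
configuration by validation AUC, and scoring the *methods themselves* by
their stability under data perturbation — half-split selection similarity
for feature selection, bootstrap AUC dispersion for classifiers. The
framework's premise is that a clinically useful method must sit in the
upper quadrant of both rankings.

## Cohort preparation

Censored survival times are dichotomized at a cutoff (default 24 months):

* label 1 — the patient was followed at least to the cutoff and was alive
  at it (survival beyond two years, or censored at exactly the cutoff);
* label 0 — death observed at or before the cutoff;
* excluded — censored before the cutoff: their two-year status is unknown.

Ties at the cutoff are resolved as "death at 24 months is a death by two
years" (label 0) and "censored at exactly 24 months completed the
follow-up window" (label 1); with continuous times these cases have
probability zero, but the convention keeps the partition exhaustive.

Z-score normalization is fit on the training cohort and applied unchanged
to validation (`zscore_fit_apply()`), which prevents validation statistics
from leaking into the model path. Whether the original benchmark
normalized each cohort against itself is not recoverable from its
description; `refit_each = TRUE` provides that alternative, and the
train-fit default is the hygienic choice. Features constant on the
training cohort are dropped (not errored) because degenerate shape
features arise naturally in synthetic and small cohorts.

## Feature selection

The fourteen filter methods share one contract: a deterministic ranking,
higher score = more relevant, ties broken by ascending feature index so
results are platform-independent.

Numerical choices that the original description leaves open, fixed here as
declared conventions:

* **Discretization** for every mutual-information-based criterion: 10
  equal-frequency bins on the normalized features (`n_bins` is
  configurable). Equal-frequency binning is robust to the heavy tails of
  radiomic intensity and texture distributions; equal-width binning is
  available. Duplicated quantile break points collapse, so heavily tied
  features occupy fewer bins — the value-to-code map stays monotone.
* **MIFS** redundancy weight β = 1, its common default (`mifs_beta`).
* **ReliefF**: k = 10 nearest hits/misses, all instances used, Manhattan
  distance, per-feature range normalization of value differences.
* **WLCX** scores are −log10 of the tie-corrected normal-approximation
  two-sided rank-sum p-value (no continuity correction), giving the same
  ordering as the statistic while keeping the uniform higher-is-better
  orientation. **CHSQ** is the chi-square statistic of the bin × class
  table; **GINI** the impurity decrease over bins; **FSCR**
  Σ n_c(μ_c − μ)² / Σ n_c σ_c² with 0/0 defined as 0.
* **CMIM** is computed through the identity
  min_s I(f;y|s) = I(f;y) − max_s [I(f;s) − I(f;s|y)]; the running maximum
  starts at −∞ because the bracket can be negative for synergistic
  features (clamping it at zero changes selections, which the
  stepwise-oracle tests catch).

All greedy criteria are arithmetic over pairwise entropy statistics that
are cached per dataset, so ranking the whole fourteen-method panel (as the
stability bootstrap does) costs little more than ranking one method.

## Classifier harness

Each of the twelve families is an adapter around an established
implementation (naive Bayes, CART, LDA, logistic regression, k-NN,
single-hidden-layer perceptron, PLS-DA, random forest, RBF SVM, gradient
boosting) with a small fixed tuning grid; bagged trees are a short
in-package bagging of CART fits, and the MARS-family member is a
hinge-basis expansion at the training quartiles with a ridge-penalized
logistic fit — an additive-splines classifier with the same shape of
decision surface. Grids are deliberately small (1–3 values per
hyperparameter) and versioned in code: the framework compares *families
under a declared, reproducible protocol*, not exhaustively tuned champions,
and the original benchmark's exact per-family configurations live in an
external catalogue that is out of scope here. This is a known limitation:
absolute AUC levels depend on the grids, the method *comparison* much less
so.

Model selection maximizes mean AUC over repeated stratified
cross-validation (default 3 × 10-fold; folds shrink with a message if the
minority class is smaller than the fold count), the final model is refit
on the full training data, and every stochastic fit draws its seed from
one master integer, so identical specs give identical models. Predictions
are continuous scores — posterior probabilities, discriminant values, or
oriented decision values — so the Mann-Whitney AUC (ties counted half) is
well-defined for every family.

## Stability

**Feature selection.** Each bootstrap iteration draws two disjoint random
halves of the training cohort, runs the method on both halves, and
compares the two top-n sets by maximum-weight bipartite matching with
|Spearman ρ| weights. Open points fixed as conventions:

* The matching total is divided by n so stability lies in [0, 1] and
  identical sets score exactly 1.
* Correlations are computed on the full training cohort, a common
  reference for both halves (`reference = "halves"` switches to the pooled
  split).
* "Bootstrap" is realized as repeated random *disjoint half-splits*,
  since the two selections must come from non-overlapping partitions.
* The selected-set size defaults to n = 30, mirroring the 30 features the
  classifier-stability protocol uses; it is a flag, and sensitivity over
  {10, 30, 50} is a one-line loop.
* A zero-variance reference feature has its correlations defined as 0
  (with a message) rather than propagating NA.

The assignment step is an in-package O(n³) shortest-augmenting-path
(Jonker–Volgenant style) solver, tested against an exhaustive-permutation
oracle; at n = 50 the matching is instantaneous.

**Classifiers.** RSD = 100·σ/μ over B = 100 validation AUCs of models
trained on random half-subsamples of the training cohort (sample standard
deviation, the small-B convention), using one fixed 30-feature Wilcoxon
selection so only the classifier varies. Lower RSD = more stable.
Subsamples that lose a class are redrawn.

## Grid evaluation, quadrants, ANOVA

`run_grid()` ranks once per selector, truncates at each subset size, and
trains every classifier per cell; failed cells are flagged, excluded from
medians (medians are robust; silent imputation would not be), and imputed
by their (selector, classifier) mean only for ANOVA, which needs balance.
Representative medians at the reference size (default 30, matching the
main reported comparison) summarize each classifier over the 14 selectors
and each selector over the 12 classifiers. `quadrant()` recomputes the
four thresholds from whatever summaries it is handed — they are medians by
construction, never hard-coded constants — and comparisons are inclusive,
so a method exactly at a threshold qualifies. The published method-level
summary table for the original NSCLC CT benchmark ships in
`inst/extdata/` and `published_benchmark()` exposes it; recomputing its
medians yields the printed thresholds 0.735 (selector stability), 0.615
(selector AUC) and 0.61 (classifier AUC) exactly. The published classifier
RSD threshold is *not* reproducible from the printed RSD column (the
column's median is 6.38 against printed values of 5.97 and 5.93 in
different places), so radbench always recomputes that threshold rather
than targeting it.

The variance decomposition is a three-factor fixed-effects ANOVA with all
two-way interactions on a balanced full-factorial grid; balance makes the
sums-of-squares types coincide, and each component is reported as its
share of the total sum of squares (eta-squared fractions). The three-way
interaction is not separable from noise with one AUC per cell and is
treated as residual.

## The synthetic cohort generator

`generate_cohort_pair()` emulates the statistical structure the analysis
assumes, not the images: four feature groups with equicorrelated
within-group structure (single-factor construction; defaults ρ =
0.5/0.3/0.5/0.4 for intensity/shape/texture/wavelet and group sizes
20/20/50/350 of 440, wavelet-dominated as in real CT panels); wavelet
features built as noisy transforms of intensity/texture parent columns
(parent correlation 0.7) plus a shared factor sized so the mean
within-wavelet correlation still matches its knob — this reproduces the
cross-group redundancy that multivariate selectors must penalize; survival
from an exponential proportional-hazards model on the summed planted
features (baseline hazard 0.035/month ≈ 43% two-year survival at baseline
risk); independent uniform censoring on a 60-month window for a
configurable fraction of patients (default 25%), which produces the
"followed less than two years" exclusions; and a mean shift (default
0.1 SD) on the validation cohort for mild between-institution drift.

`effect_size` is defined as the standardized mean difference a planted
feature shows between the two-year classes *in isolation*; the log-hazard
slope achieving it is calibrated by deterministic one-dimensional
integration (the naive choice slope = d overshoots: the
complementary-log-log label mechanism is steeper than a Gaussian shift).
With several planted features sharing the hazard, each feature's
*marginal* separation is attenuated — with five equal features a marginal
SMD of 1 per feature is in fact unattainable, since the summed risk would
need SMD √5 ≈ 2.24 and no binary label at even prevalence can induce more
than ≈ 1.6 on a Gaussian score. The parameter-recovery tests therefore
plant features at d = 2 with censoring disabled (so all 310 training
patients are labeled), which restores strong per-feature marginal signal
while staying within the intended "strongly prognostic" regime; the
recovery criterion (all five planted features in every univariate method's
top 20 of 440, in at least 95% of 50 replicates) is then met by all seven
univariate methods.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: non-Gaussian marginals and outliers,
batch effects beyond a mean shift, informative censoring, the true
correlation spectrum of CT radiomics (no published structure exists to
copy), or realistic absolute AUC levels. Synthetic validation AUCs run far
above the ≈ 0.6 of the real benchmark because planted linear signal is
easy; the framework's comparative machinery, not the absolute numbers, is
what the synthetic data exercises.

## Problem sizes used in the shipped tests

The test suite keeps each stochastic check at the smallest size where the
property has comfortable margin: correlation and closed-form AUC checks at
n = 5000; parameter recovery at the full 310 × 440 over 50 replicates;
null grids as six replicate 4 × 4 × 3 permuted-label grids with a
200-patient validation cohort (standard error of the grand mean ≈ 0.01
against the ±0.05 band); and the planted-versus-noise stability
separation with all 14 methods, 10 paired seeds and B = 10 half-splits at
p = 100, where the observed gaps (≈ 0.3) dwarf the bootstrap jitter of a
B = 10 median. The full 1,680-cell grid at default cross-validation
settings is a batch job, not part of the test run; `run_grid()` is the
same code path either way.

## Known limitations

* Tuning grids are conventions, not the external catalogue the original
  protocol referenced; absolute per-family AUCs shift with richer grids.
* Greedy criteria use plug-in MI on binned features; constants (e.g.
  DISR's normalization) may differ from specific toolbox implementations,
  so absolute criterion values are not comparable across software even
  where rankings of clear-cut cases are.
* RSD is undefined for mean AUC 0 and unstable near it; with AUCs near
  0.5–0.9 this is immaterial.
* The exponential survival model has no frailty or time-varying effects;
  only the dichotomized label feeds the downstream analysis, so richer
  survival structure would change little here.
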