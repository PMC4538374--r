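# radbench

Benchmarking machine-learning methods for radiomic survival biomarkers.

Radiomic studies extract hundreds of quantitative features (intensity,
shape, texture, wavelet) from tumor images and ask a deceptively simple
question: *which feature-selection method and which classifier should a
prognostic model use?* The answer matters twice over — a method must be
**accurate** on an independent validation cohort, and **stable** when the
training data are perturbed, or the resulting biomarker will not
generalize. radbench implements a complete evaluation framework for this
question on tabular radiomic cohorts with right-censored survival outcomes,
together with a synthetic two-cohort generator so every stage is testable
without any imaging data.

## What it computes

**Cohort preparation.** Censored survival is dichotomized at a cutoff
(default 24 months): patients followed at least to the cutoff are labeled 1
(alive at two years), deaths before the cutoff are labeled 0, and patients
censored before the cutoff are excluded. Features are Z-score normalized
with parameters fit on the training cohort and applied to validation.

**Feature selection (14 filter methods).** Univariate: Fisher score (FSCR),
ReliefF (RELF), t-score (TSCR), chi-square (CHSQ), Wilcoxon (WLCX), Gini
index (GINI), mutual-information maximization (MIM). Greedy
information-theoretic, selecting forward over criteria built from plug-in
mutual information on 10 equal-frequency bins:

| method | criterion at step k (selected set S) |
|---|---|
| MIFS | I(f;y) − β Σ_{s∈S} I(f;s) |
| MRMR | I(f;y) − (1/\|S\|) Σ_s I(f;s) |
| CIFE | I(f;y) − Σ_s [I(f;s) − I(f;s\|y)] |
| JMI  | Σ_s I({f,s};y) |
| CMIM | min_s I(f;y\|s) |
| ICAP | I(f;y) − Σ_s max(0, I(f;s) − I(f;s\|y)) |
| DISR | Σ_s I({f,s};y) / H(f,s,y) |

**Classification (12 families).** BAG, BY, BST, DT, DA, GLM, MARS, NN,
Nnet, PLSR, RF, SVM — each behind a uniform adapter with a small declared
tuning grid, trained with repeated (3×) stratified 10-fold cross-validation
maximizing AUC, refit on the full training cohort, and scored on the
validation cohort with the Mann-Whitney AUC
(ties counted half: AUC = [#(s⁺ > s⁻) + ½·#(s⁺ = s⁻)] / (n⁺ n⁻)).

**Stability.** Feature-selection stability: for each of B = 100 bootstrap
iterations the training cohort is split into two non-overlapping halves,
the method selects its top n features on each half, and the two sets are
compared by maximum-weight bipartite matching (Hungarian algorithm) with
|Spearman ρ| edge weights, normalized by the set size so the score lies in
[0, 1]; the median ± sd over iterations is reported. Classifier stability:
the relative standard deviation RSD = 100·σ/μ of 100 validation AUCs from
models trained on random half-subsamples — lower RSD means a more stable
classifier.

**Evaluation.** The full 14 × 12 × 10 grid (subset sizes 5–50 by 5) of
validation AUCs; representative medians per method at a reference size
(default 30); a quadrant report labeling methods *reliable and accurate*
when they reach the median of both their stability and their AUC ranking;
and a three-factor fixed-effects ANOVA expressing each factor's and
two-way interaction's share of the total AUC variance (eta-squared
fractions).

## Worked example

```r
library(radbench)

pair <- generate_cohort_pair(synthetic_spec(
  n_train = 310, n_val = 154, p = 100,
  group_sizes = c(intensity = 10, shape = 10, texture = 30, wavelet = 50),
  n_prognostic = 5, effect_size = 1, seed = 42))
prep <- zscore_fit_apply(pair$train, list(pair$val))
prep$train
#> <prepared_cohort> 294 labeled patients x 100 features; prevalence(label=1) 0.40; 16 excluded

rk <- rank_features(prep$train, method = "WLCX", n = 30)
rk
#> <feature_ranking> WLCX: 30 features; top: texture_027, texture_026, texture_015, texture_013, texture_021

fit <- train_cv(classifier_spec("RF", seed = 1),
                prep$train$features[, rk$ranked_ids], prep$train$label)
auc(predict(fit, prep$cohort1$features[, rk$ranked_ids]), prep$cohort1$label)
#> [1] 0.897

st <- fs_stability(prep$train, methods = c("WLCX", "MIM", "MRMR"),
                   n_features = 30, B = 20, seed = 2)
st$WLCX
#> <stability_estimate> WLCX: 0.79 +/- 0.04 (B=20, n=30)
```

The cohort pair plants five prognostic features (per-feature standardized
effect d = 1) among 100 correlated features; the Wilcoxon ranking finds
them (and their correlated texture/wavelet companions), the random forest
reaches validation AUC ≈ 0.90 on the shifted second cohort, and WLCX shows
the highest half-split selection stability of the three selectors — the
qualitative pattern the framework is designed to surface.

Method-level summaries published for the original two-cohort NSCLC CT
benchmark ship with the package:

```r
bench <- published_benchmark()
quadrant(bench$fs, bench$classifiers)
#> Reliable-and-accurate feature selection: FSCR, MIFS, MRMR, WLCX
#> ...
```

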