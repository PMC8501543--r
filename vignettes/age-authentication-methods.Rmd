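---
title: "Age authentication of American ginseng with applicability-domain-gated regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age authentication of American ginseng with applicability-domain-gated regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The market price of American ginseng (*Panax quinquefolium* L.) roots rises
steeply with cultivation age, which invites passing off young roots as old
ones. Once roots are processed, the morphological cues used at harvest are
gone, so authentication has to come from measurable physicochemical
properties. This package implements a complete authentication pipeline over
nine such features per root: HPLC-quantified contents of five ginsenosides
(Rg1, Re, Rb1, Rd, pseudo-F11), ethanol- and water-extractive mass
percentages, and the root's length and weight.

Two statistical ideas carry the pipeline. First, cultivation age (2-4
years) is regressed on the nine features with four shallow learners tuned
by grid-search cross-validation. Second — and this is the part that makes
the predictions usable in the field — every prediction is gated by a
k-nearest-neighbour distance **applicability domain** (AD): queries that do
not resemble the training material are flagged as unreliable rather than
silently mispredicted. Roots are cultivated in many regions with distinct
feature profiles, so a model trained on a few regions will inevitably meet
out-of-distribution material.

```{r, eval = FALSE}
library(ginsengAD)
cfg <- default_run_config(output_dir = "run1", seed = 1)
res <- run_pipeline(cfg)
```

## The applicability domain

Let $\bar d_{ki}$ be the mean Euclidean distance from training sample $i$
to its $k$ nearest neighbours **within the training set**, self excluded.
With $\sigma$ the standard deviation of the $\bar d_{ki}$, the domain
threshold is

$$ \mathrm{TAD} = \frac{1}{n}\sum_{i=1}^{n} \bar d_{ki} + Z\,\sigma , $$

and a query $j$ with mean distance $\mathrm{TS}_j = \bar d_{kj}$ to its $k$
nearest training samples is inside the domain iff
$\mathrm{TS}_j \le \mathrm{TAD}$. Larger $Z$ (and, more weakly, larger $k$)
loosens the domain; `ad_scan()` maps the trade-off between how many test
samples are admitted and how accurate predictions are on the admitted
subset over $k = 1..12$ and $Z$ from 0.5 towards 3.0 in steps of 0.2. The
operating point $k = 6$, $Z = 1.6$ used by `default_run_config()` sits on
the conservative side of the accuracy/coverage plateau.

Numerical conventions, chosen once and used everywhere:

* **Distances are computed in the training-standardized feature space.**
  Raw features mix mg/g, percent, cm and g; unstandardized Euclidean
  distance would be dominated by whichever feature happens to have the
  largest numeric range. `fit_ad()` on a raw matrix preserves the
  unstandardized alternative for sensitivity analyses.
* **Self-exclusion** when collecting a training sample's own neighbours;
  including self always contributes a zero distance and deflates
  $\bar d_{ki}$.
* **Sample standard deviation** ($n-1$ denominator) for $\sigma$ and for
  feature standardization, consistently across the package.
* Neighbour ties at the $k$-th distance are broken by stable index order;
  a score exactly at the threshold counts as inside (only
  $\mathrm{TS} > \mathrm{TAD}$ is unreliable).

## The regressors

`train_all_models()` tunes four algorithms by shuffled five-fold
cross-validation, stratified by age level (three discrete ages with
unequal counts make unstratified folds noisy):

* **Elastic net** via `glmnet`, parameterized by `alpha`
  ($\lambda_1+\lambda_2$) and `l1_ratio` ($\lambda_1/(\lambda_1+\lambda_2)$),
  which maps exactly onto glmnet's `(lambda, alpha)`.
* **k-NN regression** (mean or median of the $k$ neighbour labels) —
  implemented in-package since the median aggregation option is part of the
  method surface.
* **RBF support-vector regression** via `e1071::svm` (`C`, `gamma`, with
  `"scale"` resolving to $1/(d \cdot \mathrm{Var}(X))$).
* **MLP**: a small feedforward network with tanh hidden activations and a
  linear output, trained by full-batch Adam on the L2-penalized squared
  loss. It is implemented in this package (no installed R package offers a
  tanh-MLP regressor with configurable hidden layouts); training stops at
  5000 iterations or when the loss improves by less than 1e-4 for 10
  consecutive iterations, a deliberately conventional tolerance that also
  acts as mild implicit regularization on cohorts of this size.

Model selection maximizes the mean out-of-fold coefficient of
determination $R^2 = 1 - \sum_i(\hat y_i - y_i)^2 / \sum_i(y_i - \bar y)^2$;
reported CV metrics are recomputed from the pooled out-of-fold prediction
vector at the chosen candidate, and test sets are scored by MSE. Features
are standardized *inside* each fold with that fold's training statistics,
so no held-out information leaks into tuning; a property test corrupts the
test set and asserts the fitted model is unchanged. Hyperparameter ties go
to the earlier candidate in the documented grid order (grids are listed
smallest-complexity first), making selection deterministic. One printed
variant of $R^2$ circulating in the applied literature divides by
$\sum_i(\hat y_i - \bar y)^2$ instead; `r_squared(..., form = "printed")`
reproduces it, but the standard form is the default and is what the
pipeline optimizes.

The default grids (all overridable through `model_spec()` or the run
config) are conventional log-spaced ranges: elastic net
`alpha ∈ {1e-3, 1e-2, 0.1, 1, 10}` × `l1_ratio ∈ {0.1, ..., 0.9, 1}`; k-NN
`k ∈ 1..15` × `{mean, median}`; SVR `C ∈ {0.1, 1, 10, 100}` ×
`gamma ∈ {1e-3, 1e-2, 0.1, 1, scale}`; MLP hidden layouts
`{8, 16, 32, 8×8}` × `alpha ∈ {1e-4, 1e-3, 1e-2}` × learning rate
`{1e-3, 1e-2}`.

## Diagnostics

`fit_pca()` standardizes the pooled table and decomposes it by singular
values, with loading signs fixed so each component's largest-magnitude
entry is positive. The pooled (train ∪ test) standardization is a
deliberate choice for this *descriptive* diagnostic — it visualizes where
the test regions sit relative to the training cloud; the predictive
pipeline itself never uses pooled statistics. `trend_report()` summarizes
each feature by age (mean ± SD) and tests all age pairs with the classical
pooled-variance two-sample t-test, tiered at p < 0.05/0.01/0.001/0.0001.
Zero-variance group pairs, which `stats::t.test` refuses outright, are
resolved by convention: equal means give $t = 0,\ p = 1$, unequal means
$t = \pm\infty,\ p = 0$.

`fit_standard_curve()`/`quantify()` cover the upstream HPLC calibration
step: unweighted OLS of peak area on analyte amount (UV detection for the
four major ginsenosides; ELSD for pseudo-F11, with an optional log-log
transform since ELSD response is commonly linearized that way, the linear
default matching how such curves are usually reported).

## The synthetic cohort

`default_cohort_spec()` defines the cohort the test-suite runs on. It
mirrors the study design this pipeline targets, not any particular
measured dataset:

* three training regions spanning ages 2/3/4 with 64 roots in total, one
  near-distribution test region (25 four-year-old roots), one shifted test
  region (17 four-year-old roots) — the 64/25/17 layout;
* monotone age effects on weight, Rb1, Rd, Re and ethanol extractives
  (e.g. weight +3.5 g/year against 1.2 g residual noise, Rb1 +6 mg/g/year
  against 2.5 mg/g), with baselines at realistic magnitudes for 2-year
  roots;
* small region-level mean offsets among the training regions (heavier
  roots in one region, higher extractives in another);
* the shifted region displaced mainly in the extractives (+7 percentage
  points aqueous, +3 ethanol) and morphology (−6 g weight, −3 cm length),
  with moderately lower ginsenoside accumulation (−5 mg/g Rb1, −2 Re,
  −1.5 Rd). The displacement deliberately has a component along the
  age-informative direction: the scenario being emulated is a region whose
  mature roots *look young* to models trained elsewhere, which is what
  makes an ungated model dangerous and the AD necessary. Simulation across
  seeds confirms the two tendencies the suite asserts (the shifted region
  is admitted into the domain far less often than the near region, and
  every model's out-of-domain error exceeds its in-domain error) hold in
  at least 18 of 20 seeds.

Noise is independent Gaussian per feature, truncated below at zero for
contents and extractives (negligible at the default signal-to-noise);
ages are exact integers. The generator does **not** emulate correlated
measurement error, within-age maturity spread, or the covariance structure
of any real cohort — so a green test suite demonstrates the pipeline's
mechanics and its qualitative behaviour under region shift, not
quantitative performance on real roots.

## Problem sizes and determinism

The packaged analyses run at the study's natural scale: 106 samples, nine
features, five folds, the 12 × 13 scan grid. The multi-seed tendency
checks in the test suite use single-point hyperparameter grids (the
property under test concerns the AD error decomposition, not tuning),
while the acceptance script runs the full default grids. Every stochastic
component — cohort generation, fold shuffling, MLP initialization,
permutation importance — draws from an explicit seed argument, and
`run_pipeline()` threads one root seed through all stages, so identical
configs reproduce identical artifacts.

## Limitations

* Cultivation age enters as a continuous response over a narrow range
  (2-4 years); extrapolation beyond the trained age range is exactly the
  situation the AD is meant to catch, but the AD measures feature-space
  distance, not age per se.
* The AD is a single global threshold on mean k-NN distance; leverage-,
  density- or conformal-based reliability estimates are out of scope.
* Calibration starts from (amount, response) pairs; peak detection and
  integration of raw chromatograms are upstream of this package.
* With three discrete age levels, k-NN cross-validation can reach a
  perfect score on well-separated cohorts; comparisons between models near
  the ceiling are not informative there.
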