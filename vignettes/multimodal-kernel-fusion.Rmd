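---
title: "Kernel-level fusion of multimodal neuroimaging feature tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-level fusion of multimodal neuroimaging feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Case/control classification studies of developmental disorders such as ADHD
increasingly draw on several imaging modalities at once: morphometry and
intensity measures from structural MRI, diffusivity measures (FA/MD/LD/TD)
from DTI, and functional-connectivity z-scores from resting-state fMRI. Each
modality arrives as a subject-by-feature table, typically with a thousand or
so candidate features per modality, a couple of hundred subjects, and
scanner-induced batch structure. `mkfusion` implements a complete pipeline
for this setting:

1. **Batch harmonization** — location-scale empirical-Bayes (EB) removal of
   per-scanner additive and multiplicative effects, covariate-protected.
2. **All-relevant feature selection** — shadow-feature selection with a
   random-forest importance provider, plus a cross-run binomial stability
   test for reporting reproducibly selected features.
3. **Kernel-level fusion** — one Gram matrix per modality (linear or RBF),
   combined convexly with weights $w_m \ge 0$, $\sum_m w_m = 1$, inside a
   soft-margin SVM trained in the dual.
4. **Repeated nested cross-validation** — inner folds choose the kernel
   weights and the penalty $C$; outer folds estimate generalization;
   the whole procedure is repeated with fresh fold assignments.

Because the motivating cohort data are access-restricted, the package ships
a synthetic multimodal cohort generator with the same statistical skeleton,
so that every stage is testable end to end.

## The fused SVM

For training subjects $i = 1,\dots,N$ with per-modality feature vectors
$x_i^m$ and labels $y_i \in \{-1,+1\}$, the model solves

$$
\min_{\alpha}\;
\tfrac12 \sum_{i,j} \alpha_i \alpha_j y_i y_j
\sum_{m \in M} w_m\, k_m(x_i^m, x_j^m) \;-\; \sum_i \alpha_i,
\qquad
\text{s.t. } \sum_i \alpha_i y_i = 0,\; 0 \le \alpha_i \le C ,
$$

and predicts with

$$
f(x) = \operatorname{sign}\Big(
\sum_i \alpha_i^* y_i \sum_m w_m^* k_m(x_i^m, x^m) + b^* \Big).
$$

The dual is solved by SMO-style pairwise coordinate updates with
maximal-violating-pair working-set selection on the precomputed combined
Gram matrix (`solve_dual()`), stopping when the KKT gap falls below a
tolerance (default `1e-6`, at most `1e5` updates). The offset $b^*$ is
averaged over all unbounded support vectors ($0 < \alpha_i < C$) rather
than taken from a single one — numerically more stable, identical in exact
arithmetic. The solver is cross-checked in the test suite against a generic
interior-point quadratic-program solver on small random instances.

Weights are not learned by gradient descent: following the grid-search
design, every weight vector on a fixed-stride simplex grid (stride 0.1
gives 66 vectors for three modalities; `enumerate_simplex()` works on the
integer grid so no floating-point drift accumulates) is combined with every
$C$ in a log-spaced grid ($10^{-4},\dots,10^{3}$, 8 values), and each pair
is scored by mean validation AUC over the inner folds. Ties break
deterministically: fewer active kernels, then smaller $C$, then
lexicographic weight order. With a unit weight vector the machinery reduces
exactly to a single-kernel SVM, which is how the unimodal and bimodal
baselines are produced (a zero weight drops a modality).

Threshold metrics (accuracy, sensitivity, specificity, F1) are computed at
probability cutoff 0.5; probabilities come from a Platt sigmoid fitted on
the winning pair's out-of-fold inner-validation scores (the mechanism is a
package choice; the upstream description fixes only the cutoff). AUC, the
primary criterion, is rank-based (Mann–Whitney, ties half-credit) and so
identical on raw scores and calibrated probabilities.

## Kernels and standardization

Features are standardized with training-fold means and SDs before any
kernel is evaluated, so RBF distances weight features comparably. The RBF
bandwidth is unstated upstream; the default is the median heuristic
$\gamma = 1/(2\,\mathrm{med}^2)$ over pairwise training distances,
recomputed per outer fold from training rows only (parameter-free and
leakage-safe); a fixed $\gamma$ can be supplied. Per-modality kernel kinds
default to RBF for sMRI and rsfMRI and linear for DTI, the combination the
motivating study found best; both kinds are available everywhere. No kernel
centering or trace normalization is applied: after standardization the
convex combination already keeps scales commensurate, and adding it would
change the model class silently.

## Harmonization

`fit_combat()` implements the canonical parametric EB location-scale model:
feature-wise standardization against a grand mean + covariate fit, batch
location/scale estimates shrunk toward method-of-moments priors (normal for
the additive $\gamma$, inverse-gamma for the multiplicative $\delta^2$) by
iterated conditional posterior means (relative change `< 1e-4` or 100
sweeps). Two deliberate conventions:

* **Fit/apply split.** The model is estimated on the training fold and
  applied to held-out subjects from known batches (`apply_combat()`);
  fitting on the full dataset before cross-validation (the upstream
  protocol) remains available as `paper_mode`. The default avoids using
  test subjects' statistics during training.
* **Pooled variance with $n-1$.** With a single batch this makes
  fit-then-apply an exact identity (nothing to remove, nothing changed),
  at the cost of a $\sqrt{n/(n-1)}$ scale difference from harmonizers that
  divide by $n$ — immaterial at cohort sizes, and the test suite
  cross-checks against an independent whole-data implementation.

Default protected covariates are age and sex; the diagnosis label is never
accepted as a covariate. EB harmonization is *not* exactly idempotent: a
second pass re-corrects the prior-shrinkage bias of the scale posterior at
the percent level (about 0.02 pooled SD at 500 subjects per batch). The
non-EB variant (`eb = FALSE`) is idempotent to numerical precision. Both
behaviours are pinned by tests.

## Selection and the stability test

`boruta_run()` iterates shuffle–score–mark rounds: the not-yet-rejected
features are augmented with fresh shadows (independent per-column row
permutations, drawn in fixed column order so a seed reproduces the run),
everything is scored by the importance provider — by default a ranger
random forest (500 trees, $\sqrt d$ features per split) scoring
Gini-impurity decrease; any `f(x, y) -> scores` works — and features
scoring strictly above the best shadow get a hit. Hit counts are tested
each round against Binomial(rounds, ½), two-sided, Bonferroni-corrected
with a **fixed denominator equal to the candidate-pool size**. The
reference-style shrinking denominator (correct only over still-undecided
features) progressively weakens the correction as rejections accumulate;
on pure-noise data it produced a mean of ~1.4 spurious confirmations per
50-feature run, while the fixed denominator keeps it below 1. Features
still undecided at `max_iterations` are reported `tentative` and treated
as not selected (conservative).

For reporting, `stability_test()` models a feature's selection count over
$N$ fold-runs as Binomial($N$, $\hat p$), with $\hat p$ the mean fraction
of the modality's candidates selected per run; upper-tail p-values are
Holm-adjusted across the pool and flagged at 0.05.
`stability_intersection()` keeps the features significant in every
independent experiment.

## The synthetic cohort generator

`synthetic_config()` defaults encode the matched-cohort design the
pipeline targets: 116 cases / 116 controls, 45 female and 71 male per
group, race counts matched exactly between groups, age ≈ 118.4 (case) and
118.9 (control) months with SD 7.7, and candidate pools of 1184 (sMRI),
1182 (DTI) and 338 (rsfMRI) features. Features are block-exchangeable
Gaussians (blocks of 10, within-block correlation 0.3 — a simple stand-in
for the strong inter-correlation of regional brain measures); informative
features get a $+\delta$ mean shift in cases (default $\delta = 1$,
counts 4/6/10 per modality, mirroring the counts of reproducibly selected
features in the motivating study) and are spread across distinct blocks so
correlated uninformative neighbours act as decoys for the selector.
Batches (default 3) are assigned independently of the label (a confounded
mode exists but is off by default, since matched designs scan both groups
everywhere) and perturb each feature with its own additive shift
(`batch_shift * u[b, g]`) and noise-SD factor (`batch_scale^v[b, g]`),
$u, v$ fixed standard-normal draws; a single-batch cohort carries no batch
effects at all.

What the generator does **not** emulate: real marginal distributions
(volumes in mm³, FC z-scores — everything here is standardized Gaussian),
heavy tails, missingness, site-by-age interactions, or any true biological
coupling between modalities. Passing tests therefore demonstrate that the
pipeline's machinery is correct and leak-free under its stated
assumptions, not that the classifier attains any particular accuracy on
real cohort data.

## Numerical and degenerate-input choices

* Labels are `+1` (case) / `-1` (control) everywhere; anything else errors.
* Zero-variance features error at standardization; inside cross-validation
  they are dropped from a fold's selected set instead (a fold may lack
  variance a full cohort has).
* If selection confirms nothing for a modality in a fold, that fold falls
  back to all usable features (flagged in the report) — without this the
  label-permutation null could not execute the full pipeline.
* Degenerate (constant) decision scores make the Platt fit undefined; the
  calibrator warns and falls back to the plain logistic map, which reduces
  the 0.5 cutoff to the sign rule.
* `ipop`-style interior-point QP and `ksvm` exist in the ecosystem; they
  are used only as independent cross-checks in the tests, never as the
  implementation.

## Simulation sizes used by the validation suite

The packaged validation (test suite and `scripts/acceptance.R`) runs the
full pipeline on deliberately reduced problem sizes — the statistical
properties checked (type-I control, effect recovery, fusion ordering,
permutation null) are size-stable, and small instances keep the whole
suite runnable on a laptop core:

* Selection type-I: 50 pure-noise cohorts of 200 subjects × 50 features,
  100-tree forests.
* Selection recall: one default-demographics cohort with pools reduced to
  60/60/40 features, $\delta = 1$, ten training folds.
* Fusion ordering: 60 subjects per group, 40 features per modality with 5
  informative each at $\delta = 0.7$ (complementary signal split evenly so
  no modality dominates), light selection (60-tree forests, 15 rounds),
  weight stride 0.2, 10×5-fold nested CV repeated 5 times.
* Permutation null: 40 per group, pools 30/30/20, 5×3-fold CV repeated
  four times.

The generator's *defaults* are not scaled down; they stay at the full
study conditions above.

## Known limitations

* Parametric EB only; no non-parametric or GAM-based harmonization, no
  reference-batch mode, and unseen batches at apply time are an error by
  design (no extrapolation).
* The weight grid is exhaustive, so cost grows as
  $\binom{1/s + M - 1}{M - 1} \cdot |C\text{-grid}|$ inner-fold solves;
  stride 0.1 with three modalities is routine, many modalities call for a
  coarser stride.
* Binary classification only; no regression or multiclass mode.
* The stability test treats fold-runs as independent Bernoulli trials;
  overlapping training folds make it mildly anti-conservative, which is
  why reporting keeps the across-experiment intersection rule.
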