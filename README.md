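# mkfusion

Kernel-level fusion of multimodal neuroimaging feature tables for
case/control classification.

Studies of ADHD and other developmental disorders tabulate thousands of
image-derived candidate predictors per child — structural MRI morphometry
and intensity, DTI diffusivities (FA/MD/LD/TD), resting-state
functional-connectivity z-scores — across several scanners. `mkfusion`
implements the full analysis pipeline for such data:

* **Harmonization** — parametric empirical-Bayes location-scale removal of
  per-scanner batch effects (`fit_combat()` / `apply_combat()`), with a
  fit-on-training / apply-to-test split so cross-validation stays leak-free.
* **All-relevant feature selection** — shadow-feature selection driven by a
  random-forest importance provider (`boruta_run()`), plus a binomial
  selection-stability test with Holm correction across the candidate pool
  (`stability_test()`).
* **Multiple kernel learning** — per-modality Gram matrices (linear or RBF
  with median-heuristic bandwidth), fused convexly with weights searched on
  a stride-0.1 simplex grid, inside a soft-margin SVM solved in the dual by
  SMO (`solve_dual()`, `grid_search()`):

  $$\min_\alpha \tfrac12 \sum_{i,j} \alpha_i\alpha_j y_i y_j
  \sum_m w_m k_m(x_i^m, x_j^m) - \sum_i \alpha_i,
  \quad \textstyle\sum_i \alpha_i y_i = 0,\; 0 \le \alpha_i \le C,\;
  w_m \ge 0,\; \sum_m w_m = 1.$$

* **Evaluation** — repeated, stratified, nested cross-validation
  (`run_nested_cv()`): 10 outer folds estimate generalization, 5 inner
  folds pick $(w, C)$ by mean validation AUC, Platt-calibrated
  probabilities give threshold metrics at cutoff 0.5; `run_baselines()`
  adds unimodal, early-fusion, bimodal and trimodal rows on shared folds.
* **Synthetic cohorts** — `generate_cohort()` emulates a matched 116/116
  case/control design with block-correlated Gaussian features, sparse
  planted group effects and per-scanner batch effects, so the pipeline is
  fully testable without access-restricted cohort data.

## Worked example

```r
library(mkfusion)

co <- generate_cohort(synthetic_config(
  n_case = 60, n_control = 60,
  modality_dims  = c(sMRI = 40, DTI = 40, rsfMRI = 40),
  n_informative  = c(sMRI = 5,  DTI = 5,  rsfMRI = 5),
  effect_size = 0.7, seed = 5000))

plan <- cv_plan(outer_folds = 10, inner_folds = 5, repeats = 5, seed = 5001)
cfg <- pipeline_config(
  select    = TRUE,
  selection = selection_config(max_iterations = 15, num_trees = 60, seed = 5002),
  train     = train_config(stride = 0.2))

tri <- run_nested_cv(co, plan, cfg)
round(tri$summary, 3)
#>         auc    accuracy sensitivity specificity          f1
#>       0.863       0.773       0.787       0.760       0.772
```

Each row of `tri$folds` holds one outer fold's metrics together with the
inner-CV-selected kernel weights and `C`; `tri$selected` records the
features chosen per fold for the stability analysis. Here the fused model's
mean AUC (0.863) exceeds every unimodal SVM on the same folds (sMRI 0.667,
DTI 0.743, rsfMRI 0.849), because the planted signal is split across
modalities and the weight search recovers a genuinely mixed combination.

A thin command-line wrapper over the same functions is installed at
`inst/cli/mkfusion.R` (`simulate`, `harmonize`, `select`, `run-all`).

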