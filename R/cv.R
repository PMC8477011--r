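#' Cross-validation plan
#'
#' Outer K-fold cross-validation, stratified by label, repeated `repeats`
#' times with fresh fold assignments; the same subject division is shared
#' by every modality within a fold. Hyperparameters (kernel weights and C)
#' are chosen on an inner cross-validation nested inside each outer
#' training fold.
#'
#' @param outer_folds outer folds (default 10).
#' @param inner_folds nested folds (default 5).
#' @param repeats independent repetitions of the whole procedure.
#' @param seed master seed; repeat r uses `seed + r`.
#' @return a `cv_plan` list.
#' @export
cv_plan <- function(outer_folds = 10L, inner_folds = 5L, repeats = 10L,
                    seed = 1L) {
  stopifnot(outer_folds >= 2L, inner_folds >= 2L, repeats >= 1L)
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 repeats = as.integer(repeats),
                 seed = as.integer(seed)),
            class = "cv_plan")
}

#' Pipeline configuration
#'
#' Controls the per-fold pipeline: optional batch harmonization (fit on the
#' training fold, applied to the held-out fold; `paper_mode` instead fits
#' once on the whole dataset before cross-validation), optional
#' all-relevant feature selection, per-modality kernels, and the fused-SVM
#' training grid.
#'
#' @param modalities modalities to use (default: all in the cohort).
#' @param kernels named character vector of kernel kinds per modality
#'   (`"linear"` or `"rbf"`); unnamed modalities default to
#'   `default_kernels()` (rbf for sMRI and rsfMRI, linear for DTI, rbf
#'   otherwise).
#' @param harmonize run batch harmonization when more than one batch is
#'   present.
#' @param paper_mode fit harmonization once on the full dataset instead of
#'   per training fold.
#' @param combat_covariates subject columns protected by harmonization.
#' @param select run all-relevant selection per modality on each training
#'   fold. If a fold confirms nothing for a modality, all features are used
#'   for that modality in that fold (recorded in the report).
#' @param selection a [selection_config()].
#' @param train a [train_config()].
#' @param fusion `"mkl"` (one kernel per modality, weights grid-searched)
#'   or `"early"` (selected features concatenated, single kernel of kind
#'   `early_kernel`).
#' @param early_kernel kernel kind for early fusion.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(modalities = NULL, kernels = NULL,
                            harmonize = TRUE, paper_mode = FALSE,
                            combat_covariates = c("age_months", "sex"),
                            select = TRUE,
                            selection = selection_config(),
                            train = train_config(),
                            fusion = c("mkl", "early"),
                            early_kernel = "rbf") {
  fusion <- match.arg(fusion)
  structure(list(modalities = modalities, kernels = kernels,
                 harmonize = harmonize, paper_mode = paper_mode,
                 combat_covariates = combat_covariates,
                 select = select, selection = selection, train = train,
                 fusion = fusion, early_kernel = early_kernel),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
default_kernels <- function(modalities) {
  k <- ifelse(modalities == "DTI", "linear", "rbf")
  names(k) <- modalities
  k
}

covariate_matrix <- function(subjects, cols) {
  cols <- intersect(cols, names(subjects))
  if (!length(cols)) return(NULL)
  out <- lapply(cols, function(cl) {
    v <- subjects[[cl]]
    if (is.numeric(v)) v else as.numeric(factor(v)) - 1
  })
  m <- do.call(cbind, out)
  colnames(m) <- cols
  m
}

#' Run the repeated nested cross-validation pipeline
#'
#' Per outer fold: harmonize (optional), select features per modality on
#' the training fold only, standardize with training parameters, build
#' per-modality Gram matrices (RBF bandwidth from the training rows),
#' grid-search kernel weights and C on the inner cross-validation by mean
#' validation AUC, calibrate probabilities on the winning pair's
#' out-of-fold scores, retrain on the whole training fold, and evaluate on
#' the held-out fold at probability cutoff 0.5.
#'
#' @param cohort an `mk_cohort`.
#' @param plan a [cv_plan()].
#' @param config a [pipeline_config()].
#' @return an `mk_experiment`: `folds` (per-fold metrics data.frame with
#'   chosen weights and C), `summary` (means over folds and repeats),
#'   `selected` (per repeat/modality: list over folds of selected feature
#'   names), `weight_tables` (inner-CV grids, last repeat, for heatmaps).
#' @export
run_nested_cv <- function(cohort, plan = cv_plan(),
                          config = pipeline_config()) {
  stopifnot(inherits(cohort, "mk_cohort"), inherits(plan, "cv_plan"),
            inherits(config, "pipeline_config"))
  y <- cohort$subjects$label
  stopifnot(all(y %in% c(-1, 1)))
  modalities <- config$modalities %||% names(cohort$features)
  kern <- default_kernels(modalities)
  if (!is.null(config$kernels)) kern[names(config$kernels)] <- config$kernels

  feats <- cohort$features[modalities]
  batch <- cohort$subjects$batch
  covs <- covariate_matrix(cohort$subjects, config$combat_covariates)
  do_combat <- config$harmonize && length(unique(batch)) > 1L

  if (do_combat && config$paper_mode) {
    for (m in modalities) {
      cm <- fit_combat(feats[[m]], batch, covs)
      feats[[m]] <- apply_combat(cm, feats[[m]], batch, covs)
    }
  }

  rows <- list()
  selected_all <- list()
  weight_tables <- list()
  for (r in seq_len(plan$repeats)) {
    folds <- stratified_folds(y, plan$outer_folds, plan$seed + r)
    sel_rep <- stats::setNames(
      lapply(modalities, function(m) vector("list", length(folds))),
      modalities)
    for (f in seq_along(folds)) {
      test <- folds[[f]]; train <- setdiff(seq_along(y), test)
      ktr <- list(); kte <- list()
      blocks_tr <- list(); blocks_te <- list()
      n_sel <- integer(0); fellback <- FALSE
      for (m in modalities) {
        xtr <- feats[[m]][train, , drop = FALSE]
        xte <- feats[[m]][test, , drop = FALSE]
        if (do_combat && !config$paper_mode) {
          cm <- tryCatch(
            fit_combat(xtr, batch[train], covs[train, , drop = FALSE]),
            error = function(e) stop("repeat ", r, " fold ", f,
                                     " modality ", m, ": ",
                                     conditionMessage(e)))
          xtr <- apply_combat(cm, xtr, batch[train],
                              covs[train, , drop = FALSE])
          xte <- apply_combat(cm, xte, batch[test],
                              covs[test, , drop = FALSE])
        }
        if (config$select) {
          cfg <- config$selection
          cfg$seed <- cfg$seed + 1000L * r + f
          res <- boruta_run(xtr, y[train], cfg)
          sel <- res$selected
        } else {
          sel <- seq_len(ncol(xtr))
        }
        # drop zero-variance columns; fall back to all usable features if
        # nothing was confirmed (keeps the fold evaluable under the null)
        usable <- which(apply(xtr, 2L, stats::sd) > 0)
        sel <- intersect(sel, usable)
        if (!length(sel)) { sel <- usable; fellback <- TRUE }
        sel_rep[[m]][[f]] <- colnames(xtr)[sel]
        n_sel[m] <- length(sel)
        sc <- standardize_fit(xtr[, sel, drop = FALSE])
        ztr <- standardize_apply(sc, xtr[, sel, drop = FALSE])
        zte <- standardize_apply(sc, xte[, sel, drop = FALSE])
        blocks_tr[[m]] <- ztr; blocks_te[[m]] <- zte
        spec <- kernel_spec(kern[[m]])
        kk <- compute_gram(ztr, ztr, spec)
        ktr[[m]] <- kk
        kte[[m]] <- compute_gram(zte, ztr, spec, gamma = attr(kk, "gamma"))
      }
      if (config$fusion == "early") {
        ztr <- do.call(cbind, blocks_tr)
        zte <- do.call(cbind, blocks_te)
        spec <- kernel_spec(config$early_kernel)
        kk <- compute_gram(ztr, ztr, spec)
        ktr <- list(early = kk)
        kte <- list(early = compute_gram(zte, ztr, spec,
                                         gamma = attr(kk, "gamma")))
      }
      gs <- grid_search(ktr, y[train], config$train,
                        rng = plan$seed + 7919L * r + f)
      platt <- suppressWarnings(fit_platt(gs$oof_scores, y[train]))
      Ktr <- combine_kernels(ktr, gs$weights)
      sol <- solve_dual(Ktr, y[train], gs$C,
                        tol = config$train$tol,
                        max_iter = config$train$max_iter)
      Kte <- combine_kernels(kte, gs$weights)
      s <- decision_scores(sol, Kte)
      prob <- platt_prob(platt, s)
      met <- confusion_and_metrics(y[test], prob, 0.5)
      row <- data.frame(repeat_ = r, fold = f,
                        auc = auc_score(y[test], s),
                        accuracy = met$accuracy,
                        sensitivity = met$sensitivity,
                        specificity = met$specificity,
                        f1 = met$f1,
                        C = gs$C, fallback = fellback)
      for (i in seq_along(gs$weights))
        row[[paste0("w_", names(ktr)[i])]] <- gs$weights[i]
      for (m in names(n_sel)) row[[paste0("nsel_", m)]] <- n_sel[[m]]
      rows[[length(rows) + 1L]] <- row
      if (r == plan$repeats) weight_tables[[f]] <- gs$table
    }
    selected_all[[r]] <- sel_rep
  }
  folds_df <- do.call(rbind, rows)
  num <- c("auc", "accuracy", "sensitivity", "specificity", "f1")
  summary <- colMeans(folds_df[num], na.rm = TRUE)
  structure(list(folds = folds_df, summary = summary,
                 selected = selected_all,
                 weight_tables = weight_tables,
                 plan = plan, modalities = modalities),
            class = "mk_experiment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unimodal, early-fusion and multi-kernel baselines on shared folds
#'
#' Runs, with identical fold assignments so differences are paired:
#' a single-kernel SVM per modality for each requested kernel kind,
#' an early-fusion SVM on the concatenated selected features, every
#' bimodal kernel combination (the third weight pinned to zero by dropping
#' the modality), and the full multi-kernel model.
#'
#' @param cohort an `mk_cohort`.
#' @param plan a [cv_plan()].
#' @param config a [pipeline_config()] used as the template for every row.
#' @param unimodal_kernels kernel kinds evaluated per single modality.
#' @return list with `table` (one summary row per setting) and `runs`
#'   (the full `mk_experiment` objects, named as in the table).
#' @export
run_baselines <- function(cohort, plan = cv_plan(),
                          config = pipeline_config(),
                          unimodal_kernels = c("linear", "rbf")) {
  modalities <- config$modalities %||% names(cohort$features)
  runs <- list()
  add <- function(name, cfg) {
    runs[[name]] <<- run_nested_cv(cohort, plan, cfg)
  }
  for (m in modalities) {
    for (kk in unimodal_kernels) {
      cfg <- config
      cfg$modalities <- m
      cfg$kernels <- stats::setNames(kk, m)
      cfg$fusion <- "mkl"
      add(paste0(m, "_", kk, "svm"), cfg)
    }
  }
  for (kk in unimodal_kernels) {
    cfg <- config
    cfg$modalities <- modalities
    cfg$fusion <- "early"
    cfg$early_kernel <- kk
    add(paste0("early_fusion_", kk), cfg)
  }
  if (length(modalities) >= 3L) {
    pairs <- utils::combn(modalities, 2L, simplify = FALSE)
    for (pr in pairs) {
      cfg <- config
      cfg$modalities <- pr
      cfg$fusion <- "mkl"
      add(paste0("mkl_", paste(pr, collapse = "_")), cfg)
    }
  }
  cfg <- config
  cfg$modalities <- modalities
  cfg$fusion <- "mkl"
  add(paste0("mkl_", paste(modalities, collapse = "_")), cfg)

  tab <- do.call(rbind, lapply(names(runs), function(nm) {
    s <- runs[[nm]]$summary
    data.frame(setting = nm, auc = s[["auc"]], accuracy = s[["accuracy"]],
               sensitivity = s[["sensitivity"]],
               specificity = s[["specificity"]], f1 = s[["f1"]],
               stringsAsFactors = FALSE)
  }))
  list(table = tab, runs = runs)
}
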