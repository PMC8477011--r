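test_that("confusion metrics match the defining formulas", {
  # TP=6 TN=4 FP=2 FN=3
  y <- c(rep(1, 9), rep(-1, 6))
  p <- c(rep(0.9, 6), rep(0.1, 3), rep(0.9, 2), rep(0.1, 4))
  m <- confusion_and_metrics(y, p)
  expect_equal(c(m$TP, m$TN, m$FP, m$FN), c(6, 4, 2, 3))
  expect_equal(m$accuracy, 10 / 15)
  expect_equal(m$sensitivity, 6 / 9)
  expect_equal(m$specificity, 4 / 6)
  expect_equal(m$f1, 12 / 17)
  # accuracy equals class-weighted sensitivity/specificity
  P <- sum(y == 1); N <- sum(y == -1)
  expect_equal(m$accuracy, (m$sensitivity * P + m$specificity * N) / (P + N))
  perf <- confusion_and_metrics(y, (y + 1) / 2)
  expect_equal(c(perf$accuracy, perf$sensitivity, perf$specificity, perf$f1),
               rep(1, 4))
  allneg <- confusion_and_metrics(y, rep(0, 15))
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 1)
  expect_error(confusion_and_metrics(numeric(0), numeric(0)), "empty")
})

test_that("AUC equals the normalized Mann-Whitney statistic", {
  expect_equal(auc_score(c(1, 1, -1, -1), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(auc_score(c(1, -1, 1, -1), rep(0.5, 4)), 0.5)
  # pairs: 3 concordant, 1 tied of 4 -> (3 + 0.5) / 4
  expect_equal(auc_score(c(1, -1, 1, -1), c(0.9, 0.8, 0.8, 0.1)), 0.875)
  expect_equal(auc_by_pairs(c(1, -1, 1, -1), c(0.9, 0.8, 0.8, 0.1)), 0.875)
  expect_error(auc_score(c(1, 1), c(0.4, 0.2)), "both classes")
  # random inputs against explicit pair enumeration (with ties)
  for (i in 1:20) {
    set.seed(i)
    n <- sample(8:50, 1)
    y <- random_labels(n, 900 + i)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    expect_equal(auc_score(y, s), auc_by_pairs(y, s))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  y <- random_labels(60, 44)
  s <- rnorm(60) + 0.8 * y
  ref <- as.numeric(pROC::auc(pROC::roc(response = factor(y), predictor = s,
                                        quiet = TRUE, direction = "<")))
  expect_equal(auc_score(y, s), ref, tolerance = 1e-12)
})

test_that("stratified folds partition subjects and keep both classes", {
  y <- random_labels(53, 55)
  folds <- stratified_folds(y, 5, seed = 3)
  expect_setequal(unlist(folds), seq_along(y))
  expect_equal(sum(lengths(folds)), length(y))
  for (f in folds) expect_equal(sort(unique(y[f])), c(-1, 1))
  expect_identical(folds, stratified_folds(y, 5, seed = 3))
  expect_error(stratified_folds(rep(c(1, -1), c(50, 3)), 5, 1),
               "single-class")
})

test_that("nested CV partitions subjects once per repeat and is deterministic", {
  co <- tiny_cohort(seed = 61L)
  plan <- cv_plan(outer_folds = 4, inner_folds = 3, repeats = 2, seed = 7)
  cfg <- pipeline_config(select = FALSE,
                         train = train_config(C_grid = c(0.1, 1, 10),
                                              stride = 0.5, inner_folds = 3))
  e1 <- run_nested_cv(co, plan, cfg)
  expect_equal(nrow(e1$folds), 8L)
  expect_true(all(table(e1$folds$repeat_) == 4L))
  e2 <- run_nested_cv(co, plan, cfg)
  expect_identical(e1$folds, e2$folds)
  expect_named(e1$summary,
               c("auc", "accuracy", "sensitivity", "specificity", "f1"))
  expect_true(all(e1$summary >= 0 & e1$summary <= 1))
})

test_that("an overwhelming signal is classified perfectly through the pipeline", {
  co <- tiny_cohort(seed = 62L, n = 20L, dims = c(A = 6L, B = 6L, C = 6L),
                    info = c(A = 4L, B = 0L, C = 0L), delta = 8, batches = 1L)
  e <- run_nested_cv(co, cv_plan(outer_folds = 4, inner_folds = 3,
                                 repeats = 1, seed = 5),
                     pipeline_config(select = FALSE,
                                     train = train_config(
                                       C_grid = c(0.1, 1, 10),
                                       stride = 0.5, inner_folds = 3)))
  expect_equal(unname(e$summary[["accuracy"]]), 1)
  expect_equal(unname(e$summary[["auc"]]), 1)
})

test_that("early fusion of a single modality reduces to that unimodal SVM", {
  co <- tiny_cohort(seed = 63L, n = 18L)
  plan <- cv_plan(outer_folds = 3, inner_folds = 3, repeats = 1, seed = 2)
  tc <- train_config(C_grid = c(0.1, 1), stride = 1, inner_folds = 3)
  uni <- run_nested_cv(co, plan,
                       pipeline_config(modalities = "A",
                                       kernels = c(A = "rbf"),
                                       select = FALSE, train = tc))
  early <- run_nested_cv(co, plan,
                         pipeline_config(modalities = "A", fusion = "early",
                                         early_kernel = "rbf",
                                         select = FALSE, train = tc))
  expect_equal(uni$summary, early$summary, tolerance = 1e-10)
})

test_that("baseline table covers unimodal, early-fusion, bimodal and trimodal rows", {
  co <- tiny_cohort(seed = 64L, n = 15L, dims = c(A = 6L, B = 6L, C = 6L),
                    info = c(A = 2L, B = 2L, C = 2L), delta = 1.5,
                    batches = 1L)
  bl <- run_baselines(co,
                      cv_plan(outer_folds = 3, inner_folds = 3, repeats = 1,
                              seed = 4),
                      pipeline_config(select = FALSE,
                                      train = train_config(
                                        C_grid = c(0.1, 1), stride = 0.5,
                                        inner_folds = 3)))
  expect_equal(nrow(bl$table), 3 * 2 + 2 + 3 + 1)
  expect_equal(sum(grepl("^mkl_", bl$table$setting)), 4L)  # 3 bimodal + 1
  expect_true(all(bl$table$auc >= 0 & bl$table$auc <= 1))
})

test_that("selection results are carried per repeat, modality and fold", {
  co <- tiny_cohort(seed = 65L, n = 20L, dims = c(A = 10L, B = 8L, C = 8L),
                    info = c(A = 3L, B = 0L, C = 0L), delta = 3,
                    batches = 1L)
  e <- run_nested_cv(co, cv_plan(outer_folds = 3, inner_folds = 3,
                                 repeats = 1, seed = 6),
                     pipeline_config(
                       select = TRUE,
                       selection = selection_config(max_iterations = 15L,
                                                    num_trees = 60L,
                                                    seed = 3L),
                       train = train_config(C_grid = c(0.1, 1), stride = 0.5,
                                            inner_folds = 3)))
  sel <- e$selected[[1]]
  expect_named(sel, c("A", "B", "C"))
  expect_length(sel$A, 3L)
  expect_true(all(vapply(sel$A, is.character, TRUE)))
})
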