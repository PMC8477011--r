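#' Append shadow features to a matrix
#'
#' Shadow features are independent row-permutations of the original
#' columns: they keep each feature's marginal distribution but break any
#' relation to the label, providing the importance null that all-relevant
#' selection tests against. Columns `d+1..2d` of the result are shadows of
#' columns `1..d`, permuted column-by-column in fixed column order so a
#' seeded RNG reproduces the augmentation exactly.
#'
#' @param x numeric matrix with at least 2 rows.
#' @return matrix with `2 * ncol(x)` columns; shadow columns are named
#'   `shadow_<original>`.
#' @export
shadow_augment <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("shadow_augment() needs at least 2 rows")
  d <- ncol(x)
  sh <- x
  for (j in seq_len(d)) sh[, j] <- x[sample.int(nrow(x)), j]
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("V", seq_len(d))
  colnames(sh) <- paste0("shadow_", nm)
  cbind(x, sh)
}

#' Random-forest importance provider
#'
#' Builds the default importance provider used by [boruta_run()]: a ranger
#' random forest scoring every column by total Gini-impurity decrease. Any
#' function with signature `f(x, y) -> non-negative score per column` can
#' stand in (the selection algorithm only consumes scores).
#'
#' @param num_trees trees per forest.
#' @param mtry features tried per split; default `floor(sqrt(ncol(x)))`.
#' @return a provider function.
#' @export
rf_importance_provider <- function(num_trees = 500L, mtry = NULL) {
  force(num_trees); force(mtry)
  function(x, y) {
    m <- if (is.null(mtry)) max(1L, floor(sqrt(ncol(x)))) else mtry
    fit <- ranger::ranger(
      x = as.data.frame(x), y = factor(y),
      num.trees = num_trees, mtry = m,
      importance = "impurity",
      num.threads = 1L,
      seed = sample.int(.Machine$integer.max, 1L))
    unname(fit$variable.importance)
  }
}

#' Selection configuration
#'
#' @param max_iterations cap on shuffle-score-mark rounds.
#' @param alpha significance level of the per-round two-sided binomial hit
#'   test (Bonferroni-corrected over the candidate-feature pool).
#' @param num_trees ensemble size per round for the default provider.
#' @param mtry features per split for the default provider.
#' @param seed RNG seed for shadows and forests.
#' @return a `selection_config` list.
#' @export
selection_config <- function(max_iterations = 100L, alpha = 0.05,
                             num_trees = 500L, mtry = NULL, seed = 1L) {
  stopifnot(max_iterations >= 1L, alpha > 0, alpha < 1)
  structure(list(max_iterations = as.integer(max_iterations), alpha = alpha,
                 num_trees = as.integer(num_trees), mtry = mtry,
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' All-relevant feature selection with shadow features
#'
#' Iterates: augment the not-yet-rejected features with fresh shadows,
#' score all columns with the importance provider, and mark a "hit" for
#' every undecided feature scoring strictly above the best shadow. After
#' each round, each undecided feature's hit count is tested against
#' Binomial(rounds, 1/2), two-sided with Bonferroni correction over the
#' candidate-feature pool: significantly many hits confirms the feature,
#' significantly few rejects it. The loop ends when no feature is
#' undecided or after `max_iterations` rounds; features still undecided
#' are reported `tentative` and treated as not selected.
#'
#' @param x subjects x features matrix.
#' @param y labels (two classes; any coding).
#' @param config a [selection_config()].
#' @param importance_provider `f(x, y) -> score per column`; defaults to a
#'   ranger Gini-impurity forest per `config`.
#' @return a `selection_result`: per-feature `status`
#'   (confirmed/rejected/tentative), `hits`, `trials`, `selected` (indices
#'   of confirmed features), `iterations`.
#' @export
boruta_run <- function(x, y, config = selection_config(),
                       importance_provider = NULL) {
  stopifnot(inherits(config, "selection_config"))
  x <- as.matrix(x)
  d <- ncol(x)
  if (d == 0L) stop("no features to select from")
  if (all(apply(x, 2L, function(col) stats::sd(col) == 0)))
    stop("all features are constant")
  if (is.null(importance_provider))
    importance_provider <- rf_importance_provider(config$num_trees,
                                                  config$mtry)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  status <- rep("tentative", d)
  hits <- integer(d)
  trials <- integer(d)
  it <- 0L
  while (any(status == "tentative") && it < config$max_iterations) {
    it <- it + 1L
    active <- which(status != "rejected")      # kept in the forest
    undecided <- which(status == "tentative")
    xa <- shadow_augment(x[, active, drop = FALSE])
    imp <- importance_provider(xa, y)
    if (length(imp) != ncol(xa))
      stop("importance provider returned ", length(imp),
           " scores for ", ncol(xa), " columns")
    da <- length(active)
    imp_orig <- imp[seq_len(da)]
    max_shadow <- max(imp[(da + 1L):(2L * da)])
    hit_now <- active[imp_orig > max_shadow]
    hit_und <- intersect(hit_now, undecided)
    hits[hit_und] <- hits[hit_und] + 1L
    trials[undecided] <- trials[undecided] + 1L

    # Bonferroni over the full candidate pool (not just the still-undecided
    # features): keeping the denominator fixed preserves type-I control as
    # rejections accumulate
    p_up <- stats::pbinom(hits[undecided] - 1L, trials[undecided], 0.5,
                          lower.tail = FALSE)
    p_dn <- stats::pbinom(hits[undecided], trials[undecided], 0.5)
    p_two <- pmin(1, 2 * pmin(p_up, p_dn))
    confirm <- p_two < config$alpha / d &
      hits[undecided] > trials[undecided] / 2
    reject <- p_two < config$alpha / d &
      hits[undecided] < trials[undecided] / 2
    status[undecided[confirm]] <- "confirmed"
    status[undecided[reject]] <- "rejected"
  }
  structure(list(status = status, hits = hits, trials = trials,
                 selected = which(status == "confirmed"),
                 tentative = which(status == "tentative"),
                 iterations = it,
                 feature_names = colnames(x)),
            class = "selection_result")
}

#' Binomial selection-stability test across repeated runs
#'
#' Under the null that a selector picks features at random, a feature's
#' selection count over `N` runs is Binomial(N, p), with p estimated as
#' the mean fraction of the modality's candidate features selected per run.
#' Each feature's upper-tail p-value is Holm-adjusted across the modality's
#' whole candidate pool and flagged significant below `alpha`.
#'
#' @param selected_sets list of integer index vectors (or character vectors
#'   resolved via `feature_names`), one per run.
#' @param modality_dim size of the candidate-feature pool.
#' @param alpha significance level after Holm adjustment.
#' @param feature_names optional names for the candidate pool.
#' @return a `stability_report` data.frame (feature, count, frequency,
#'   p_value, p_holm, significant) with attributes `p_hat` and `N`.
#' @export
stability_test <- function(selected_sets, modality_dim, alpha = 0.05,
                           feature_names = NULL) {
  if (!length(selected_sets)) stop("no selection runs supplied")
  N <- length(selected_sets)
  if (is.null(feature_names))
    feature_names <- paste0("f", seq_len(modality_dim))
  sets <- lapply(selected_sets, function(s) {
    if (is.character(s)) s <- match(s, feature_names)
    s <- as.integer(s)
    if (any(is.na(s)) || any(s < 1L) || any(s > modality_dim))
      stop("selected indices outside the candidate pool")
    s
  })
  p_hat <- mean(vapply(sets, length, 1L) / modality_dim)
  count <- tabulate(unlist(sets), nbins = modality_dim)
  p_value <- stats::pbinom(count - 1L, N, p_hat, lower.tail = FALSE)
  p_holm <- stats::p.adjust(p_value, method = "holm")
  out <- data.frame(feature = feature_names, count = count,
                    frequency = count / N,
                    p_value = p_value, p_holm = p_holm,
                    significant = p_holm < alpha,
                    stringsAsFactors = FALSE)
  attr(out, "p_hat") <- p_hat
  attr(out, "N") <- N
  class(out) <- c("stability_report", "data.frame")
  out
}

#' Intersection of significant features over independent experiments
#'
#' Combines stability reports from repeated independent experiments and
#' flags the features significant in every one of them.
#'
#' @param reports list of `stability_report` objects over the same pool.
#' @return the first report augmented with an `intersection` column.
#' @export
stability_intersection <- function(reports) {
  stopifnot(length(reports) >= 1L)
  sig <- Reduce(`&`, lapply(reports, function(r) r$significant))
  out <- reports[[1L]]
  out$intersection <- sig
  out
}

#' Selected-subset percentage of a candidate pool
#'
#' The reporting convenience used to express an average selected-subset
#' size as a percentage of the modality's candidate-feature pool.
#'
#' @param mean_size average number of selected features per run.
#' @param n_candidates candidate-pool size.
#' @return percentage (0-100 scale).
#' @export
selection_percentage <- function(mean_size, n_candidates) {
  stopifnot(n_candidates > 0)
  100 * mean_size / n_candidates
}

#' Summarize selection runs per modality
#'
#' @param selected_sets list of per-run selected index vectors.
#' @param modality_dim candidate-pool size.
#' @return data.frame with mean size and percentage of the pool.
#' @export
summarize_selection <- function(selected_sets, modality_dim) {
  sizes <- vapply(selected_sets, length, 1L)
  data.frame(mean_size = mean(sizes),
             pct_of_pool = selection_percentage(mean(sizes), modality_dim))
}
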