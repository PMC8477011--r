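#' Solve the multiple-kernel SVM dual on a precomputed Gram matrix
#'
#' Minimizes
#' \deqn{\tfrac12 \sum_{ij} \alpha_i \alpha_j y_i y_j K_{ij} - \sum_i \alpha_i}
#' subject to \eqn{\sum_i \alpha_i y_i = 0} and \eqn{0 \le \alpha_i \le C},
#' by SMO-style pairwise coordinate updates with maximal-violating-pair
#' selection. `K` is normally the convex combination of per-modality Gram
#' matrices from [combine_kernels()]; with a single kernel this is the
#' ordinary soft-margin SVM dual.
#'
#' The offset `b` is averaged over all unbounded support vectors
#' (`0 < alpha_i < C`), for which the KKT conditions pin the margin; when
#' none exist the midpoint of the feasible offset interval is used.
#'
#' @param K square symmetric PSD Gram matrix over the training subjects.
#' @param y labels in \{-1, +1\}, both classes present.
#' @param C box constraint (misclassification penalty).
#' @param tol KKT-gap stopping tolerance.
#' @param max_iter cap on pairwise updates.
#' @return an `mk_dual` object: `alpha`, `b`, `C`, `objective` (dual value),
#'   `support` (indices with alpha above tolerance), `ids` (training subject
#'   ids if `K` had dimnames), `y`, convergence diagnostics.
#' @export
solve_dual <- function(K, y, C, tol = 1e-6, max_iter = 1e5) {
  K <- unclass(K)
  if (!is.matrix(K) || nrow(K) != ncol(K)) stop("K must be a square matrix")
  y <- as.numeric(y)
  if (length(y) != nrow(K)) stop("length(y) must match nrow(K)")
  if (!all(y %in% c(-1, 1))) stop("y must be coded -1/+1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (!is.finite(C) || C <= 0) stop("C must be positive")
  fit <- smo_solve_cpp(K, y, C, tol, as.integer(max_iter))
  alpha <- fit$alpha
  sv <- which(alpha > 1e-8 * max(1, C))
  structure(list(alpha = alpha, b = fit$b, C = C, y = y,
                 objective = fit$objective,
                 support = sv,
                 ids = rownames(K),
                 iterations = fit$iterations, kkt_gap = fit$kkt_gap,
                 n_free_sv = fit$n_free_sv),
            class = "mk_dual")
}

#' Decision scores for new subjects
#'
#' `score(x) = sum_i alpha_i y_i K(x, x_i) + b`; the predicted label is its
#' sign. `K_cross` has one row per evaluation subject and one column per
#' training subject, in the training order the solver saw.
#'
#' @param sol an `mk_dual` from [solve_dual()].
#' @param K_cross evaluation-by-training (combined) Gram matrix.
#' @return numeric vector of real-valued decision scores.
#' @export
decision_scores <- function(sol, K_cross) {
  stopifnot(inherits(sol, "mk_dual"))
  K_cross <- unclass(K_cross)
  if (is.null(dim(K_cross))) K_cross <- matrix(K_cross, nrow = 1L)
  if (ncol(K_cross) != length(sol$alpha))
    stop("K_cross columns must align with training subjects")
  if (!is.null(sol$ids) && !is.null(colnames(K_cross)) &&
      !identical(colnames(K_cross), sol$ids))
    stop("training-subject ids misaligned between model and kernel")
  drop(K_cross %*% (sol$alpha * sol$y)) + sol$b
}

#' @rdname decision_scores
#' @export
predict_labels <- function(sol, K_cross) {
  s <- decision_scores(sol, K_cross)
  ifelse(s >= 0, 1, -1)
}

#' Platt sigmoid calibration of decision scores
#'
#' Fits `P(y = +1 | s) = 1 / (1 + exp(A s + B))` by Newton iteration on the
#' regularized log-loss (targets smoothed to (N+ + 1)/(N+ + 2) and
#' 1/(N- + 2)), so the 0.5 probability cutoff corresponds to the score
#' threshold `-B/A`. A converged fit on separable-in-the-right-direction
#' scores has `A < 0` (probability increasing in score).
#'
#' With degenerate (all-equal) scores the fit is undefined; the function
#' warns and falls back to the plain logistic map of the raw score, which
#' reduces the 0.5 cutoff to the sign rule.
#'
#' @param scores decision scores (ideally out-of-fold).
#' @param y labels in \{-1, +1\}.
#' @return an `mk_platt` object with coefficients `A`, `B`.
#' @export
fit_platt <- function(scores, y) {
  y <- as.numeric(y)
  stopifnot(length(scores) == length(y), all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (stats::sd(scores) < .Machine$double.eps * 100) {
    warning("degenerate (constant) decision scores; falling back to sign rule")
    return(structure(list(A = -1, B = 0, fallback = TRUE), class = "mk_platt"))
  }
  prior1 <- sum(y > 0); prior0 <- sum(y < 0)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(y > 0, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  sigma <- 1e-12; max_it <- 100L; min_step <- 1e-10
  fval <- platt_obj(A, B, scores, t)
  for (it in seq_len(max_it)) {
    fApB <- A * scores + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(scores * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(scores^2 * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(scores * d2)
    det <- h11 * h22 - h21^2
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    while (step >= min_step) {
      newA <- A + step * dA; newB <- B + step * dB
      newf <- platt_obj(newA, newB, scores, t)
      if (newf < fval + 1e-4 * step * gd) {
        A <- newA; B <- newB; fval <- newf
        break
      }
      step <- step / 2
    }
    if (step < min_step) break
  }
  structure(list(A = A, B = B, fallback = FALSE), class = "mk_platt")
}

platt_obj <- function(A, B, scores, t) {
  fApB <- A * scores + B
  sum(ifelse(fApB >= 0,
             t * fApB + log1p(exp(-fApB)),
             (t - 1) * fApB + log1p(exp(fApB))))
}

#' @rdname fit_platt
#' @param platt an `mk_platt` object.
#' @export
platt_prob <- function(platt, scores) {
  stopifnot(inherits(platt, "mk_platt"))
  1 / (1 + exp(platt$A * scores + platt$B))
}

#' Training configuration for the fused SVM
#'
#' @param C_grid penalty grid; default eight log-spaced values
#'   \eqn{10^{-4} \ldots 10^{3}}.
#' @param stride kernel-weight grid stride on the simplex.
#' @param inner_folds folds of the nested (inner) cross-validation that
#'   scores each (weights, C) pair.
#' @param tol,max_iter solver controls passed to [solve_dual()].
#' @return a `train_config` list.
#' @export
train_config <- function(C_grid = 10^(-4:3), stride = 0.1,
                         inner_folds = 5L, tol = 1e-6, max_iter = 1e5) {
  stopifnot(all(C_grid > 0), inner_folds >= 2L)
  structure(list(C_grid = C_grid, stride = stride,
                 inner_folds = as.integer(inner_folds),
                 tol = tol, max_iter = max_iter),
            class = "train_config")
}

#' Grid search over kernel weights and C by inner cross-validation
#'
#' For every simplex weight vector and every C, solves the fused dual on
#' each inner-training split and scores the inner-validation subjects; the
#' pair maximizing mean inner AUC wins. Ties break deterministically toward
#' fewer nonzero weights, then smaller C, then lexicographic weight order.
#' The full (weights x C) table is returned for weight-heatmap inspection,
#' together with the out-of-fold validation scores of the winning pair
#' (used downstream for Platt calibration).
#'
#' @param kernels list of square training Gram matrices, one per modality,
#'   identical subject order.
#' @param y training labels (-1/+1).
#' @param config a [train_config()].
#' @param weights_grid optional matrix of weight rows overriding the simplex
#'   enumeration (e.g. a single unit vector for a unimodal fit).
#' @param rng an RNG seed (integer) controlling inner-fold assignment.
#' @return list: `weights`, `C`, `table` (one row per pair with mean inner
#'   AUC), `oof_scores`, `oof_index`, `folds`.
#' @export
grid_search <- function(kernels, y, config = train_config(),
                        weights_grid = NULL, rng = 1L) {
  stopifnot(inherits(config, "train_config"))
  M <- length(kernels)
  if (is.null(weights_grid)) {
    weights_grid <- if (M == 1L) matrix(1, 1L, 1L) else
      enumerate_simplex(config$stride, M)
  }
  folds <- stratified_folds(y, config$inner_folds, rng)
  n_w <- nrow(weights_grid); n_c <- length(config$C_grid)
  auc_sum <- matrix(0, n_w, n_c)
  oof <- array(NA_real_, c(n_w, n_c, length(y)))
  for (w_i in seq_len(n_w)) {
    Kw <- combine_kernels(kernels, weights_grid[w_i, ])
    for (f in seq_along(folds)) {
      val <- folds[[f]]; tr <- setdiff(seq_along(y), val)
      Ktr <- Kw[tr, tr, drop = FALSE]
      Kcv <- Kw[val, tr, drop = FALSE]
      for (c_i in seq_len(n_c)) {
        sol <- solve_dual(Ktr, y[tr], config$C_grid[c_i],
                          tol = config$tol, max_iter = config$max_iter)
        s <- decision_scores(sol, Kcv)
        oof[w_i, c_i, val] <- s
        auc_sum[w_i, c_i] <- auc_sum[w_i, c_i] + auc_score(y[val], s)
      }
    }
  }
  mean_auc <- auc_sum / length(folds)
  # deterministic tie-breaking: max AUC, fewest active kernels, smallest C,
  # lexicographically first weight row
  nz <- rowSums(weights_grid > 0)
  best <- which(mean_auc == max(mean_auc), arr.ind = TRUE)
  ord <- order(nz[best[, 1L]], config$C_grid[best[, 2L]], best[, 1L])
  pick <- best[ord[1L], ]
  tab <- data.frame(
    weight_index = rep(seq_len(n_w), times = n_c),
    C = rep(config$C_grid, each = n_w),
    mean_auc = as.vector(mean_auc)
  )
  tab <- cbind(tab, weights_grid[tab$weight_index, , drop = FALSE])
  names(tab)[-(1:3)] <- paste0("w", seq_len(M))
  list(weights = weights_grid[pick[1L], ],
       C = config$C_grid[pick[2L]],
       mean_auc = mean_auc[pick[1L], pick[2L]],
       table = tab,
       oof_scores = oof[pick[1L], pick[2L], ],
       folds = folds)
}
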