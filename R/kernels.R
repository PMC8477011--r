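#' Fit a column standardizer on training data
#'
#' Computes per-feature means and standard deviations on the training rows
#' only, so that held-out subjects can be transformed with training
#' parameters without leakage. Standardization makes squared Euclidean
#' distances comparable across features, which the RBF kernel requires.
#'
#' @param x_train numeric matrix (subjects x features) with column names.
#' @return an object of class `mk_scaler` holding per-column `center` and
#'   `scale`.
#' @export
standardize_fit <- function(x_train) {
  x_train <- as.matrix(x_train)
  if (nrow(x_train) < 2L) stop("standardize_fit() needs at least 2 rows")
  center <- colMeans(x_train)
  scale <- apply(x_train, 2L, stats::sd)
  zero <- which(scale <= .Machine$double.eps * 10)
  if (length(zero)) {
    nm <- colnames(x_train)[zero]
    if (is.null(nm)) nm <- as.character(zero)
    stop("zero-variance feature(s) cannot be standardized: ",
         paste(utils::head(nm, 5L), collapse = ", "))
  }
  structure(list(center = center, scale = scale,
                 features = colnames(x_train)),
            class = "mk_scaler")
}

#' Apply a fitted standardizer
#'
#' @param scaler an `mk_scaler` from [standardize_fit()].
#' @param x matrix to transform; columns must match the training features.
#' @return the standardized matrix.
#' @export
standardize_apply <- function(scaler, x) {
  stopifnot(inherits(scaler, "mk_scaler"))
  x <- as.matrix(x)
  if (!is.null(scaler$features) && !is.null(colnames(x))) {
    if (!identical(colnames(x), scaler$features)) {
      if (!all(scaler$features %in% colnames(x))) {
        stop("feature-name mismatch between scaler and data")
      }
      x <- x[, scaler$features, drop = FALSE]
    }
  } else if (ncol(x) != length(scaler$center)) {
    stop("feature-count mismatch between scaler and data")
  }
  sweep(sweep(x, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}

#' Describe a kernel
#'
#' @param kind `"linear"` or `"rbf"`.
#' @param bandwidth for RBF kernels, either `"median"` (the median
#'   heuristic: gamma = 1 / (2 * median(d)^2) over pairwise training
#'   Euclidean distances) or a fixed positive numeric gamma.
#' @return a `kernel_spec` object.
#' @export
kernel_spec <- function(kind = c("linear", "rbf"), bandwidth = "median") {
  kind <- match.arg(kind)
  if (kind == "rbf") {
    if (is.numeric(bandwidth)) {
      if (length(bandwidth) != 1L || !is.finite(bandwidth) || bandwidth <= 0)
        stop("fixed gamma must be a single positive number")
    } else if (!identical(bandwidth, "median")) {
      stop("bandwidth must be \"median\" or a positive gamma")
    }
  }
  structure(list(kind = kind, bandwidth = bandwidth), class = "kernel_spec")
}

#' Median-heuristic RBF bandwidth
#'
#' gamma = 1 / (2 * m^2) where m is the median pairwise Euclidean distance
#' among the training rows (zero distances from duplicated rows excluded).
#'
#' @param x_train training matrix (rows already standardized).
#' @return gamma (scalar).
#' @export
median_heuristic_gamma <- function(x_train) {
  d <- stats::dist(as.matrix(x_train))
  d <- d[d > 0]
  if (!length(d)) stop("median heuristic undefined: all training rows identical")
  m <- stats::median(d)
  1 / (2 * m^2)
}

#' Compute a Gram matrix between two row sets
#'
#' Rows of the result index `xa` (evaluation subjects), columns index `xb`
#' (reference subjects, normally the training set). For a square training
#' Gram pass the same matrix twice.
#'
#' @param xa,xb matrices sharing feature columns.
#' @param spec a [kernel_spec()]. For an RBF spec with the median-heuristic
#'   bandwidth, `gamma` is derived from `xb` (the reference/training rows).
#' @param gamma optional precomputed gamma overriding the spec rule.
#' @return a `kernel_matrix`: the Gram values with attributes `spec`,
#'   `gamma`, and any row/column names carried over from the inputs.
#' @export
compute_gram <- function(xa, xb, spec, gamma = NULL) {
  stopifnot(inherits(spec, "kernel_spec"))
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  if (ncol(xa) != ncol(xb)) stop("dimension mismatch between row sets")
  if (spec$kind == "linear") {
    k <- tcrossprod(xa, xb)
    gamma <- NA_real_
  } else {
    if (is.null(gamma)) {
      gamma <- if (is.numeric(spec$bandwidth)) spec$bandwidth else
        median_heuristic_gamma(xb)
    }
    # ||a-b||^2 = ||a||^2 + ||b||^2 - 2 a.b, clipped at 0 for roundoff
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
    d2[d2 < 0] <- 0
    k <- exp(-gamma * d2)
  }
  structure(k, spec = spec, gamma = gamma, class = c("kernel_matrix", "matrix"))
}

#' Convex combination of per-modality Gram matrices
#'
#' Entrywise sum of `weights[m] * kernels[[m]]`. A zero weight drops a
#' modality from the fused kernel (the mechanism used for bimodal and
#' unimodal restrictions of the trimodal model).
#'
#' @param kernels list of Gram matrices with identical dimensions and
#'   subject ordering (checked via dimnames when present).
#' @param weights numeric vector on the simplex (non-negative, summing to 1).
#' @return the combined Gram matrix.
#' @export
combine_kernels <- function(kernels, weights) {
  if (length(kernels) != length(weights))
    stop("one weight per kernel required")
  if (any(weights < -1e-12)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  dims <- lapply(kernels, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("kernel dimension mismatch")
  dn <- dimnames(kernels[[1L]])
  for (k in kernels[-1L]) {
    dnk <- dimnames(k)
    if (!is.null(dn) && !is.null(dnk) && !identical(dn, dnk))
      stop("subject-order mismatch across kernels; refusing to reorder")
  }
  out <- matrix(0, nrow(kernels[[1L]]), ncol(kernels[[1L]]), dimnames = dn)
  for (m in seq_along(kernels)) {
    if (weights[m] != 0) out <- out + weights[m] * unclass(kernels[[m]])
  }
  structure(out, class = c("kernel_matrix", "matrix"))
}

#' Enumerate the kernel-weight simplex on a fixed-stride grid
#'
#' All weight vectors with entries in {0, stride, 2*stride, ..., 1} summing
#' to exactly 1, in deterministic lexicographic order. Arithmetic is done on
#' the integer grid (k / (1/stride)) so no floating-point drift accumulates;
#' stride 0.1 with three modalities yields the 66 compositions of 10 into 3
#' non-negative parts.
#'
#' @param stride grid stride; 1/stride must be an integer.
#' @param n_modalities number of kernels being fused.
#' @return a matrix with one weight vector per row.
#' @export
enumerate_simplex <- function(stride, n_modalities) {
  stopifnot(n_modalities >= 1L)
  k <- 1 / stride
  if (abs(k - round(k)) > 1e-9) stop("stride must divide 1 exactly")
  k <- as.integer(round(k))
  combos <- compositions_of(k, n_modalities)
  combos / k
}

# integer compositions of total into n parts, lexicographic by first part asc.
compositions_of <- function(total, n) {
  if (n == 1L) return(matrix(total, 1L, 1L))
  out <- NULL
  for (first in 0:total) {
    rest <- compositions_of(total - first, n - 1L)
    out <- rbind(out, cbind(first, rest))
  }
  dimnames(out) <- NULL
  out
}
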