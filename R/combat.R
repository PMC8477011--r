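#' Fit a location-scale empirical-Bayes batch-harmonization model
#'
#' Parametric empirical-Bayes harmonization of scanner/batch effects in
#' feature tables (the ComBat model): each feature is decomposed into a
#' grand mean, covariate effects, an additive per-batch shift gamma and a
#' multiplicative per-batch scale delta^2. Per-batch estimates are shrunk
#' toward a common prior across features (normal prior for gamma,
#' inverse-gamma for delta^2, hyperparameters by method of moments) via
#' iterated conditional posterior means.
#'
#' Unlike whole-dataset harmonizers, the model is split into fit and apply
#' steps so it can be estimated on a training fold and applied to held-out
#' subjects from the same batches without leakage.
#'
#' @param table numeric matrix, subjects x features.
#' @param batch batch id per subject (coerced to factor); every batch needs
#'   at least 2 subjects.
#' @param covariates optional numeric design columns (no intercept) whose
#'   effects must be preserved, e.g. age and sex. The diagnosis label must
#'   never be included here.
#' @param eb use empirical-Bayes shrinkage (TRUE) or raw per-batch
#'   location/scale estimates (FALSE).
#' @param tol,max_iter stopping rule for the EB posterior iteration
#'   (maximum relative parameter change below `tol`, or `max_iter` sweeps).
#' @return a `combat_model`.
#' @export
fit_combat <- function(table, batch, covariates = NULL, eb = TRUE,
                       tol = 1e-4, max_iter = 100L) {
  x <- as.matrix(table)
  n <- nrow(x); p <- ncol(x)
  if (anyNA(x)) stop("missing values are not supported")
  batch <- factor(batch)
  if (length(batch) != n) stop("batch length must match nrow(table)")
  nb <- table(batch)
  if (any(nb < 2L))
    stop("batch(es) with fewer than 2 subjects (variance undefined): ",
         paste(names(nb)[nb < 2L], collapse = ", "))
  bdes <- vapply(levels(batch), function(l) as.numeric(batch == l),
                 numeric(n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates must match nrow(table)")
    design <- cbind(bdes, covariates)
  } else {
    design <- bdes
  }
  if (qr(design)$rank < ncol(design))
    stop("design (batch + covariates) is rank-deficient")

  beta <- solve(crossprod(design), crossprod(design, x))
  n_batches <- nlevels(batch)
  gamma_hat_raw <- beta[seq_len(n_batches), , drop = FALSE]
  grand_mean <- drop(crossprod(as.numeric(nb) / n,
                               gamma_hat_raw))           # weighted by size
  resid <- x - design %*% beta
  sigma2 <- colSums(resid^2) / (n - 1)
  low <- sigma2 <= .Machine$double.eps * 100
  if (any(low)) {
    nm <- colnames(x)[low]
    if (is.null(nm)) nm <- as.character(which(low))
    stop("constant feature(s) within standardization: ",
         paste(utils::head(nm, 5L), collapse = ", "))
  }
  sigma <- sqrt(sigma2)

  cov_fit <- if (is.null(covariates)) matrix(0, n, p) else
    covariates %*% beta[-seq_len(n_batches), , drop = FALSE]
  z <- sweep(sweep(x - cov_fit, 2L, grand_mean, "-"), 2L, sigma, "/")

  gamma_hat <- matrix(NA_real_, n_batches, p)
  delta2_hat <- matrix(NA_real_, n_batches, p)
  for (b in seq_len(n_batches)) {
    zb <- z[batch == levels(batch)[b], , drop = FALSE]
    gamma_hat[b, ] <- colMeans(zb)
    delta2_hat[b, ] <- colSums(sweep(zb, 2L, gamma_hat[b, ])^2) /
      (nrow(zb) - 1)
  }

  if (eb) {
    post <- eb_posteriors(gamma_hat, delta2_hat, as.numeric(nb), z, batch,
                          tol, max_iter)
    gamma_star <- post$gamma_star
    delta2_star <- post$delta2_star
    hyper <- post$hyper
  } else {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
    hyper <- NULL
  }

  structure(list(grand_mean = grand_mean,
                 beta_cov = if (is.null(covariates)) NULL else
                   beta[-seq_len(n_batches), , drop = FALSE],
                 sigma = sigma,
                 gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                 gamma_star = gamma_star, delta2_star = delta2_star,
                 hyper = hyper, eb = eb,
                 batch_levels = levels(batch),
                 n_per_batch = as.numeric(nb),
                 features = colnames(x)),
            class = "combat_model")
}

# method-of-moments inverse-gamma hyperparameters
ig_a <- function(d) { m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2 }
ig_b <- function(d) { m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2 }

eb_posteriors <- function(gamma_hat, delta2_hat, nb, z, batch, tol, max_iter) {
  n_batches <- nrow(gamma_hat)
  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  hyper <- vector("list", n_batches)
  for (b in seq_len(n_batches)) {
    g <- gamma_hat[b, ]; d <- delta2_hat[b, ]
    gbar <- mean(g); tau2 <- stats::var(g)
    s2d <- stats::var(d)
    degenerate <- !is.finite(tau2) || tau2 < 1e-12 ||
      !is.finite(s2d) || s2d < 1e-12
    if (degenerate) {
      # exchangeability across features is exact; nothing to shrink
      hyper[[b]] <- list(gamma_bar = gbar, tau2 = tau2,
                         a = NA_real_, b = NA_real_, degenerate = TRUE)
      next
    }
    a <- ig_a(d); bb <- ig_b(d)
    zb <- z[batch == levels(batch)[b], , drop = FALSE]
    g_new <- g; d_new <- d
    g_old <- g; d_old <- d
    for (it in seq_len(max_iter)) {
      g_new <- (nb[b] * tau2 * g + d_old * gbar) / (nb[b] * tau2 + d_old)
      sum2 <- colSums(sweep(zb, 2L, g_new)^2)
      d_new <- (0.5 * sum2 + bb) / (nb[b] / 2 + a - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new; d_old <- d_new
      if (change < tol) break
    }
    gamma_star[b, ] <- g_new
    delta2_star[b, ] <- d_new
    hyper[[b]] <- list(gamma_bar = gbar, tau2 = tau2, a = a, b = bb,
                       degenerate = FALSE)
  }
  if (any(delta2_star <= 0)) stop("non-positive posterior scale estimate")
  list(gamma_star = gamma_star, delta2_star = delta2_star, hyper = hyper)
}

#' Apply a fitted harmonization model
#'
#' Standardizes each feature with the training grand mean, covariate fit
#' and pooled SD, removes the batch location/scale estimates
#' `(z - gamma*) / delta*`, and restores the grand mean and covariate
#' effects. Subjects must come from batches seen at fit time.
#'
#' @param model a `combat_model` from [fit_combat()].
#' @param table subjects x features matrix (same features as at fit).
#' @param batch batch ids; all must be known to the model.
#' @param covariates covariate columns matching the fit (required if the
#'   model was fit with covariates).
#' @return the harmonized matrix, same shape as `table`.
#' @export
apply_combat <- function(model, table, batch, covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  x <- as.matrix(table)
  if (ncol(x) != length(model$sigma)) stop("feature-count mismatch with model")
  if (!is.null(model$features) && !is.null(colnames(x)) &&
      !identical(colnames(x), model$features))
    stop("feature names do not match the fitted model")
  batch <- as.character(batch)
  unseen <- setdiff(unique(batch), model$batch_levels)
  if (length(unseen))
    stop("batch id(s) not seen at fit time: ", paste(unseen, collapse = ", "))
  has_cov <- !is.null(model$beta_cov)
  if (has_cov && is.null(covariates))
    stop("model was fit with covariates; provide them")
  cov_fit <- if (has_cov) as.matrix(covariates) %*% model$beta_cov else
    matrix(0, nrow(x), ncol(x))
  z <- sweep(sweep(x - cov_fit, 2L, model$grand_mean, "-"), 2L,
             model$sigma, "/")
  bi <- match(batch, model$batch_levels)
  z_adj <- (z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta2_star[bi, , drop = FALSE])
  out <- sweep(z_adj, 2L, model$sigma, "*") +
    cov_fit + matrix(model$grand_mean, nrow(x), ncol(x), byrow = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Serialize / restore a harmonization model as JSON
#'
#' @param model a `combat_model`.
#' @param path file path.
#' @export
write_combat_model <- function(model, path) {
  stopifnot(inherits(model, "combat_model"))
  obj <- unclass(model)
  obj$gamma_hat <- NULL; obj$delta2_hat <- NULL; obj$hyper <- NULL
  obj <- obj[!vapply(obj, is.null, TRUE)]
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_combat_model
#' @export
read_combat_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("gamma_star", "delta2_star")) obj[[f]] <- as.matrix(obj[[f]])
  if (length(obj$beta_cov)) obj$beta_cov <- as.matrix(obj$beta_cov) else
    obj$beta_cov <- NULL
  if (length(obj$batch_levels) == 1L) {
    # single-row matrices arrive as vectors; restore shape
    for (f in c("gamma_star", "delta2_star"))
      obj[[f]] <- matrix(obj[[f]], nrow = 1L)
  }
  obj$eb <- as.logical(obj$eb)
  structure(obj, class = "combat_model")
}
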