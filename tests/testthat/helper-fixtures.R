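# Small cohort/problem factories shared across test files.

tiny_cohort <- function(seed = 5L, n = 24L, dims = c(A = 12L, B = 12L, C = 8L),
                        info = c(A = 3L, B = 0L, C = 0L), delta = 1.5,
                        batches = 2L) {
  generate_cohort(synthetic_config(
    n_case = n, n_control = n,
    modality_dims = dims, n_informative = info,
    effect_size = delta, block_corr = 0.2, block_size = 4L,
    n_batches = batches, batch_shift = 0.3, batch_scale = 1.1,
    seed = seed))
}

# random strictly PSD Gram matrix
random_psd <- function(n, seed) {
  set.seed(seed)
  a <- matrix(rnorm(n * n), n)
  crossprod(a) / n + diag(1e-4, n)
}

random_labels <- function(n, seed) {
  set.seed(seed)
  y <- sample(c(-1, 1), n, replace = TRUE)
  while (length(unique(y)) < 2L) y <- sample(c(-1, 1), n, replace = TRUE)
  y
}

# generic box-constrained QP oracle for the SVM dual (kernlab interior point)
qp_dual_oracle <- function(K, y, C) {
  n <- length(y)
  Q <- (y %*% t(y)) * K
  qp <- kernlab::ipop(c = rep(-1, n), H = Q, A = t(y), b = 0,
                      l = rep(0, n), u = rep(C, n), r = 0, sigf = 7)
  a <- kernlab::primal(qp)
  list(alpha = a, objective = drop(0.5 * t(a) %*% Q %*% a - sum(a)))
}

# AUC by explicit enumeration of case-control pairs (ties half credit)
auc_by_pairs <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}
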