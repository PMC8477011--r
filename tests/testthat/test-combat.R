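# direct two-batch generator: unit Gaussian noise, known additive shift
two_batch_sim <- function(n_per, p, shift, seed, covariate = FALSE) {
  set.seed(seed)
  n <- 2L * n_per
  batch <- rep(1:2, each = n_per)
  x <- matrix(rnorm(n * p), n, p)
  x[batch == 2L, ] <- x[batch == 2L, ] + shift
  cov <- if (covariate) cbind(age = rnorm(n, 119, 7)) else NULL
  if (covariate) x <- x + 0.05 * cov[, 1L] %o% rep(1, p)
  list(x = x, batch = batch, cov = cov)
}

test_that("single-batch fit leaves the data untouched", {
  sim <- two_batch_sim(40L, 15L, 0, seed = 1L)
  m <- fit_combat(sim$x, rep(1L, nrow(sim$x)))
  out <- apply_combat(m, sim$x, rep(1L, nrow(sim$x)))
  expect_lt(max(abs(out - sim$x)), 1e-8)
  expect_lt(max(abs(m$gamma_star)), 1e-12)
  expect_lt(max(abs(m$delta2_star - 1)), 1e-12)
})

test_that("a planted additive batch shift is recovered within 5%", {
  sim <- two_batch_sim(500L, 60L, 2.0, seed = 2L)
  m <- fit_combat(sim$x, sim$batch)
  # gamma* are in standardized units; pooled sigma excludes the batch-mean
  # component, so the planted shift of 2.0 should reappear directly
  rec <- mean((m$gamma_star[2L, ] - m$gamma_star[1L, ]) * m$sigma)
  expect_lt(abs(rec - 2.0) / 2.0, 0.05)
})

# per-feature (heterogeneous) batch effects, as scanners produce: each
# feature gets its own additive shift and multiplicative scale in batch 2
hetero_batch_sim <- function(n_per, p, seed, shift_sd = 1, scale_base = 1.5) {
  set.seed(seed)
  batch <- rep(1:2, each = n_per)
  x <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
  shift <- rnorm(p, sd = shift_sd)
  scale <- scale_base^rnorm(p)
  x[batch == 2L, ] <- sweep(sweep(x[batch == 2L, ], 2L, scale, "*"),
                            2L, shift, "+")
  list(x = x, batch = batch, shift = shift, scale = scale)
}

test_that("harmonization removes batch means and equalizes variances", {
  sim <- hetero_batch_sim(500L, 40L, seed = 3L)
  x <- sim$x; batch <- sim$batch
  m <- fit_combat(x, batch)
  out <- apply_combat(m, x, batch)
  pooled_sd <- apply(out, 2L, sd)
  mean_gap <- abs(colMeans(out[batch == 1L, ]) - colMeans(out[batch == 2L, ]))
  expect_lt(max(mean_gap / pooled_sd), 0.05)
  vr <- apply(out[batch == 1L, ], 2L, var) / apply(out[batch == 2L, ], 2L, var)
  expect_true(all(vr > 0.8 & vr < 1.25))
})

test_that("EB estimates shrink toward the per-batch prior mean", {
  sim <- two_batch_sim(50L, 80L, 0.8, seed = 4L)
  m <- fit_combat(sim$x, sim$batch)
  for (b in 1:2) {
    gbar <- m$hyper[[b]]$gamma_bar
    expect_true(all(abs(m$gamma_star[b, ] - gbar) <=
                      abs(m$gamma_hat[b, ] - gbar) + 1e-12))
  }
})

test_that("harmonizing already-harmonized data is a near no-op", {
  sim <- hetero_batch_sim(500L, 30L, seed = 5L)
  # without shrinkage the second pass finds nothing left to remove
  m1 <- fit_combat(sim$x, sim$batch, eb = FALSE)
  once <- apply_combat(m1, sim$x, sim$batch)
  m2 <- fit_combat(once, sim$batch, eb = FALSE)
  twice <- apply_combat(m2, once, sim$batch)
  pooled_sd <- apply(once, 2L, sd)
  expect_lt(max(abs(twice - once)) / min(pooled_sd), 5e-3)
  # EB re-shrinkage re-corrects its own prior bias at the percent level,
  # bounded well below the batch effects it removed
  m1 <- fit_combat(sim$x, sim$batch)
  once <- apply_combat(m1, sim$x, sim$batch)
  m2 <- fit_combat(once, sim$batch)
  twice <- apply_combat(m2, once, sim$batch)
  expect_lt(max(abs(twice - once)) / min(pooled_sd), 0.05)
})

test_that("label effects survive harmonization when batch is independent", {
  set.seed(6)
  n <- 400L; p <- 20L
  y <- rep(c(1, -1), each = n / 2)
  batch <- sample(rep(1:2, each = n / 2))
  x <- matrix(rnorm(n * p), n, p)
  x[batch == 2L, ] <- x[batch == 2L, ] + 0.5
  x[y == 1, 1:5] <- x[y == 1, 1:5] + 1.0
  m <- fit_combat(x, batch)
  out <- apply_combat(m, x, batch)
  smd <- function(v) (mean(v[y == 1]) - mean(v[y == -1])) /
    sqrt((var(v[y == 1]) + var(v[y == -1])) / 2)
  for (j in 1:5) {
    before <- smd(x[, j]); after <- smd(out[, j])
    expect_lt(abs(after - before) / abs(before), 0.10)
  }
})

test_that("covariate slopes are preserved", {
  sim <- two_batch_sim(400L, 10L, 1.0, seed = 7L, covariate = TRUE)
  m <- fit_combat(sim$x, sim$batch, sim$cov)
  out <- apply_combat(m, sim$x, sim$batch, sim$cov)
  for (j in 1:5) {
    b_before <- coef(lm(sim$x[, j] ~ sim$cov[, 1L] + factor(sim$batch)))[2L]
    b_after <- coef(lm(out[, j] ~ sim$cov[, 1L]))[2L]
    expect_lt(abs(b_after - b_before), 0.02)
  }
})

test_that("agrees with the reference whole-data harmonizer", {
  skip_if_not_installed("sva")
  sim <- two_batch_sim(200L, 50L, 1.0, seed = 8L, covariate = TRUE)
  m <- fit_combat(sim$x, sim$batch, sim$cov)
  mine <- apply_combat(m, sim$x, sim$batch, sim$cov)
  mod <- stats::model.matrix(~ sim$cov[, 1L])
  ref <- suppressMessages(
    t(sva::ComBat(dat = t(sim$x), batch = sim$batch, mod = mod)))
  # conventions differ only in the pooled-variance denominator (n-1 vs n),
  # a 1/(2n) relative effect at this size
  expect_lt(max(abs(mine - ref)), 0.01)
})

test_that("contract violations raise labelled errors", {
  sim <- two_batch_sim(20L, 5L, 0.5, seed = 9L)
  expect_error(fit_combat(sim$x, c(rep(1L, nrow(sim$x) - 1L), 2L)),
               "fewer than 2")
  xc <- sim$x; xc[, 3L] <- 7; colnames(xc) <- paste0("f", 1:5)
  expect_error(fit_combat(xc, sim$batch), "f3")
  m <- fit_combat(sim$x, sim$batch)
  expect_error(apply_combat(m, sim$x, rep(3L, nrow(sim$x))), "not seen")
})

test_that("models serialize and restore through JSON", {
  sim <- two_batch_sim(50L, 8L, 1.0, seed = 10L)
  m <- fit_combat(sim$x, sim$batch)
  path <- withr::local_tempfile(fileext = ".json")
  write_combat_model(m, path)
  m2 <- read_combat_model(path)
  out1 <- apply_combat(m, sim$x, sim$batch)
  out2 <- apply_combat(m2, sim$x, sim$batch)
  expect_equal(out1, out2, tolerance = 1e-12)
})
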