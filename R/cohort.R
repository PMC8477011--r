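#' Configuration for the synthetic multimodal cohort generator
#'
#' The generator emulates the statistical structure of tabulated
#' neuroimaging-derived feature tables from a matched case/control cohort:
#' three modalities of block-correlated Gaussian features, a sparse set of
#' group-separating ("informative") features per modality, scanner batches
#' with additive and multiplicative effects, and matched demographics.
#' Defaults mirror a 116/116 matched ADHD/control design (45 female and 71
#' male per group, age about 118.5 +/- 7.7 months) with candidate-feature
#' pools of 1184 (sMRI), 1182 (DTI) and 338 (rsfMRI).
#'
#' @param n_case,n_control subjects per group.
#' @param sex_split named counts `c(female=, male=)` per group; rescaled
#'   proportionally when group sizes differ from the default.
#' @param modality_dims named feature counts per modality.
#' @param n_informative named counts of group-separating features.
#' @param effect_size standardized mean difference (case minus control, in
#'   pooled-SD units) planted on each informative feature.
#' @param block_corr within-block exchangeable correlation rho in [0, 1).
#' @param block_size features per correlated block.
#' @param n_batches number of scanner batches.
#' @param batch_shift additive batch-effect scale: batch b shifts feature g
#'   by `batch_shift * u[b, g]`, with u fixed standard-normal draws.
#' @param batch_scale multiplicative batch-effect base: noise SD multiplied
#'   by `batch_scale^v[b, g]`, v fixed standard-normal draws.
#' @param confounded_batch if TRUE, batch assignment probabilities depend on
#'   the label (off by default: groups are scanner-matched).
#' @param age_mean_case,age_mean_control,age_sd age model, months.
#' @param race_split named per-group counts, matched exactly between groups.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_case = 116L, n_control = 116L,
                             sex_split = c(female = 45L, male = 71L),
                             modality_dims = c(sMRI = 1184L, DTI = 1182L,
                                               rsfMRI = 338L),
                             n_informative = c(sMRI = 4L, DTI = 6L,
                                               rsfMRI = 10L),
                             effect_size = 1.0,
                             block_corr = 0.3, block_size = 10L,
                             n_batches = 3L,
                             batch_shift = 0.5, batch_scale = 1.25,
                             confounded_batch = FALSE,
                             age_mean_case = 118.4, age_mean_control = 118.9,
                             age_sd = 7.7,
                             race_split = c(White = 80L, Hispanic = 13L,
                                            Black = 10L, Asian = 12L,
                                            Other = 1L),
                             seed = 1L) {
  stopifnot(n_case >= 0, n_control >= 0, all(modality_dims >= 0),
            all(n_informative >= 0), n_batches >= 1L,
            block_corr >= 0, block_corr < 1, block_size >= 1L,
            batch_scale > 0)
  if (!identical(names(modality_dims), names(n_informative)))
    stop("modality_dims and n_informative must name the same modalities")
  if (any(modality_dims == 0 & n_informative > 0))
    stop("cannot plant informative features in a zero-dimension modality")
  if (any(n_informative > modality_dims))
    stop("n_informative cannot exceed modality_dims")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic multimodal cohort
#'
#' Features are drawn from a block-exchangeable Gaussian (correlation
#' `block_corr` within consecutive blocks of `block_size` features, unit
#' marginal variance). Informative features get a `+effect_size` mean shift
#' in cases and are spread across distinct blocks so that correlated
#' uninformative neighbours act as selection decoys. Batch assignment is
#' independent of the label unless `confounded_batch`; batch b then adds
#' `batch_shift * u[b, g]` to feature g and multiplies its noise by
#' `batch_scale^v[b, g]`. Ground-truth informative indices are recorded
#' (synthetic cohorts only).
#'
#' @param config a [synthetic_config()].
#' @return an `mk_cohort`: `subjects` (data.frame with subject_id, label in
#'   \{+1 case, -1 control\}, batch, age_months, sex, race), `features`
#'   (named list of subject-by-feature matrices), `truth` (per-modality
#'   informative indices and the batch-effect draws), `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_case == 0L || config$n_control == 0L)
    stop("both groups must be non-empty")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_case + config$n_control
  ids <- sprintf("S%04d", seq_len(n))
  label <- c(rep(1L, config$n_case), rep(-1L, config$n_control))

  sex <- c(group_sex(config$n_case, config$sex_split),
           group_sex(config$n_control, config$sex_split))
  race <- c(group_race(config$n_case, config$race_split),
            group_race(config$n_control, config$race_split))
  age <- numeric(n)
  age[label == 1L] <- stats::rnorm(config$n_case, config$age_mean_case,
                                   config$age_sd)
  age[label == -1L] <- stats::rnorm(config$n_control, config$age_mean_control,
                                    config$age_sd)

  batch <- draw_batches(label, config$n_batches, config$confounded_batch)

  truth <- list()
  features <- list()
  for (m in names(config$modality_dims)) {
    d <- config$modality_dims[[m]]
    if (d == 0L) next
    k <- config$n_informative[[m]]
    rho <- config$block_corr
    bs <- min(config$block_size, d)
    n_blocks <- ceiling(d / bs)
    block_of <- rep(seq_len(n_blocks), each = bs)[seq_len(d)]
    z <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
    eps <- matrix(stats::rnorm(n * d), n, d)
    resid <- sqrt(rho) * z[, block_of, drop = FALSE] + sqrt(1 - rho) * eps

    # batch effects: per-(batch, feature) fixed draws (none with one batch)
    u <- matrix(stats::rnorm(config$n_batches * d), config$n_batches, d)
    v <- matrix(stats::rnorm(config$n_batches * d), config$n_batches, d)
    if (config$n_batches == 1L) { u[] <- 0; v[] <- 0 }
    sd_mult <- config$batch_scale^v
    x <- resid * sd_mult[batch, , drop = FALSE] +
      config$batch_shift * u[batch, , drop = FALSE]

    info <- informative_indices(k, d, bs, n_blocks)
    if (k > 0L) {
      x[label == 1L, info] <- x[label == 1L, info] + config$effect_size
    }
    colnames(x) <- sprintf("%s_f%04d", m, seq_len(d))
    rownames(x) <- ids
    features[[m]] <- x
    truth[[m]] <- list(informative = info,
                       informative_names = colnames(x)[info],
                       batch_shift_u = u, batch_scale_v = v)
  }

  subjects <- data.frame(subject_id = ids, label = label, batch = batch,
                         age_months = age, sex = sex, race = race,
                         stringsAsFactors = FALSE)
  structure(list(subjects = subjects, features = features,
                 truth = truth, config = config),
            class = "mk_cohort")
}

# spread k informative features over distinct blocks (round-robin)
informative_indices <- function(k, d, block_size, n_blocks) {
  if (k == 0L) return(integer(0))
  idx <- integer(k)
  for (i in seq_len(k)) {
    blk <- (i - 1L) %% n_blocks
    off <- (i - 1L) %/% n_blocks
    idx[i] <- blk * block_size + off + 1L
  }
  idx <- idx[idx <= d]
  if (length(idx) < k) idx <- sort(unique(c(idx, seq_len(d))))[seq_len(k)]
  sort(idx)
}

group_sex <- function(n, split) {
  f <- round(n * split[["female"]] / sum(split))
  c(rep("F", f), rep("M", n - f))
}

group_race <- function(n, split) {
  cnt <- largest_remainder(n, split / sum(split))
  rep(names(split), times = cnt)
}

# apportion n into integer counts proportional to p (largest remainder)
largest_remainder <- function(n, p) {
  raw <- n * p
  cnt <- floor(raw)
  left <- n - sum(cnt)
  if (left > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(left)]] <- cnt[ord[seq_len(left)]] + 1
  }
  as.integer(cnt)
}

draw_batches <- function(label, n_batches, confounded) {
  n <- length(label)
  if (n_batches == 1L) return(rep(1L, n))
  probs_case <- rep(1 / n_batches, n_batches)
  probs_ctrl <- probs_case
  if (confounded) {
    # tilt cases toward low-index batches
    w <- rev(seq_len(n_batches))
    probs_case <- w / sum(w)
    probs_ctrl <- rev(probs_case)
  }
  for (try in 1:100) {
    b <- integer(n)
    b[label == 1L] <- sample.int(n_batches, sum(label == 1L), replace = TRUE,
                                 prob = probs_case)
    b[label == -1L] <- sample.int(n_batches, sum(label == -1L), replace = TRUE,
                                  prob = probs_ctrl)
    if (all(tabulate(b, n_batches) >= 2L)) return(b)
  }
  stop("could not assign at least 2 subjects to every batch; reduce n_batches")
}

#' Write / read a cohort as delimited text
#'
#' One comma-delimited table per modality (`<modality>.csv`, first column
#' `subject_id`), a `meta.csv` with subject metadata, and `truth.json` with
#' the synthetic ground truth. Values round-trip at full precision.
#'
#' @param cohort an `mk_cohort`.
#' @param directory output directory (created if missing).
#' @return `write_cohort` returns the directory invisibly; `read_cohort`
#'   returns the reconstructed `mk_cohort` (without the generator config).
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "mk_cohort"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (m in names(cohort$features)) {
    df <- data.frame(subject_id = cohort$subjects$subject_id,
                     cohort$features[[m]], check.names = FALSE)
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     file.path(directory, paste0(m, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  meta <- cohort$subjects
  meta$age_months <- format(meta$age_months, digits = 17, trim = TRUE,
                            scientific = FALSE)
  utils::write.csv(meta, file.path(directory, "meta.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- lapply(cohort$truth, function(t)
    list(informative = t$informative,
         informative_names = t$informative_names))
  jsonlite::write_json(truth, file.path(directory, "truth.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(directory)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  meta_path <- file.path(directory, "meta.csv")
  if (!file.exists(meta_path)) stop("meta.csv not found in ", directory)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  required <- c("subject_id", "label", "batch")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("meta.csv is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (length(unique(meta$label)) != 2L)
    stop("label column must take exactly two values")
  files <- setdiff(list.files(directory, pattern = "\\.csv$"), "meta.csv")
  features <- list()
  for (f in files) {
    m <- sub("\\.csv$", "", f)
    tab <- utils::read.csv(file.path(directory, f), check.names = FALSE,
                           stringsAsFactors = FALSE)
    if (names(tab)[1L] != "subject_id")
      stop("first column of ", f, " must be subject_id")
    if (!identical(tab$subject_id, meta$subject_id))
      stop("subject ids in ", f, " do not match meta.csv")
    x <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(x) <- "double"
    rownames(x) <- tab$subject_id
    features[[m]] <- x
  }
  truth <- NULL
  tj <- file.path(directory, "truth.json")
  if (file.exists(tj)) {
    truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  }
  structure(list(subjects = meta, features = features, truth = truth,
                 config = NULL),
            class = "mk_cohort")
}

#' @export
print.mk_cohort <- function(x, ...) {
  cat("Multimodal cohort:", nrow(x$subjects), "subjects (",
      sum(x$subjects$label == 1L), "case /",
      sum(x$subjects$label == -1L), "control ),",
      length(unique(x$subjects$batch)), "batch(es)\n")
  for (m in names(x$features))
    cat("  ", m, ": ", ncol(x$features[[m]]), " features\n", sep = "")
  invisible(x)
}
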