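# Random-forest evaluation: stratified k-fold cross-validation with pooled
# confusion counts, incremental feature selection over an mRMR ranking, and
# repeated balanced undersampling for imbalanced data.

#' @keywords internal
as_xy <- function(samples, y = NULL) {
  if (inherits(samples, "ppi_samples")) {
    list(X = samples$X, y = samples$y,
         width = samples$width, per_dim = samples$per_dim)
  } else {
    X <- as.matrix(samples)
    if (is.null(y)) stop("y must be supplied when samples is a plain matrix")
    list(X = X, y = as.integer(y), width = 1L, per_dim = ncol(X))
  }
}

#' @keywords internal
rf_fit_predict <- function(Xtr, ytr, Xte, n_trees, seed) {
  colnames(Xtr) <- colnames(Xte) <- paste0("x", seq_len(ncol(Xtr)))
  fit <- ranger::ranger(x = as.data.frame(Xtr),
                        y = factor(ytr, levels = c(0L, 1L)),
                        num.trees = n_trees, seed = seed,
                        num.threads = 1L, verbose = FALSE)
  pred <- stats::predict(fit, data = as.data.frame(Xte),
                         num.threads = 1L, verbose = FALSE)$predictions
  as.integer(as.character(pred))
}

#' @keywords internal
make_folds <- function(y, k, seed, stratified = TRUE) {
  n <- length(y)
  if (k < 2L || k > n) stop("fold count k must be in [2, n_samples]")
  fold <- integer(n)
  withr::with_seed(seed, {
    if (stratified) {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      fold[] <- sample(rep_len(seq_len(k), n))
    }
  })
  fold
}

#' Cross-validated random-forest evaluation
#'
#' Splits the samples into k stratified, seeded folds; trains a random
#' forest (majority vote of `n_trees` decision trees) on each training
#' split and predicts the held-out fold; pools the per-fold confusion
#' counts into a single table and computes the five metrics once on the
#' pooled counts.
#'
#' @param samples A `ppi_samples` object, or a numeric matrix with `y`
#'   given separately.
#' @param y Binary labels (only when `samples` is a matrix).
#' @param n_trees Number of trees (default 197, the tuned forest size).
#' @param k Number of folds (default 10; the study sweeps 3-10).
#' @param seed Integer seed controlling fold assignment and tree induction.
#' @param stratified Stratify folds by class (default `TRUE`).
#' @return List of class `ppi_cv`: `metrics` (see [compute_metrics()]),
#'   `counts` (pooled `ppi_confusion`), `fold` (per-sample fold id), `k`,
#'   `n_trees`, `seed`.
#' @examples
#' sim <- simulate_feature_dataset(n_samples = 120, n_informative = 3,
#'                                 n_noise = 2, effect_size = 2,
#'                                 positive_fraction = 0.5, seed = 1)
#' cv <- cross_validate(sim$X, sim$y, n_trees = 50, k = 3, seed = 1)
#' cv$metrics
#' @export
cross_validate <- function(samples, y = NULL, n_trees = 197L, k = 10L,
                           seed = 1L, stratified = TRUE) {
  d <- as_xy(samples, y)
  if (length(unique(d$y)) != 2L) {
    stop("degenerate data: both classes must be present")
  }
  fold <- make_folds(d$y, k, seed, stratified)
  counts <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (f in seq_len(k)) {
    te <- which(fold == f)
    if (!length(te)) next
    tr <- which(fold != f)
    pred <- rf_fit_predict(d$X[tr, , drop = FALSE], d$y[tr],
                           d$X[te, , drop = FALSE],
                           n_trees = n_trees, seed = seed + f)
    counts <- counts + unclass(confusion_counts(d$y[te], pred))
  }
  class(counts) <- "ppi_confusion"
  structure(list(metrics = compute_metrics(counts), counts = counts,
                 fold = fold, k = k, n_trees = n_trees, seed = seed),
            class = "ppi_cv")
}

#' Rank the per-residue feature catalog of a sample set
#'
#' Applies [mrmr_rank()] to the center residue's feature block of each
#' sample, producing an ordering of the per-residue feature catalog (the
#' 40 features in the default encoding) regardless of window or patch
#' width. For window samples the center is the middle position; for patch
#' samples it is the first.
#'
#' @param samples A `ppi_samples` object.
#' @inheritParams mrmr_rank
#' @return A `ppi_mrmr` ranking over the `per_dim` catalog features.
#' @export
mrmr_rank_samples <- function(samples, scheme = c("MID", "MIQ"), alpha = 1) {
  stopifnot(inherits(samples, "ppi_samples"))
  center_pos <- if (samples$mode == "window") (samples$width + 1L) %/% 2L else 1L
  cols <- (center_pos - 1L) * samples$per_dim + seq_len(samples$per_dim)
  mrmr_rank(samples$X[, cols, drop = FALSE], samples$y,
            scheme = scheme, alpha = alpha)
}

#' @keywords internal
expand_feature_columns <- function(features, width, per_dim) {
  # catalog feature f occupies column f + per_dim*(pos-1) at each position
  as.vector(outer(features, per_dim * (seq_len(width) - 1L), `+`))
}

#' Incremental feature selection
#'
#' Walks the mRMR ranking of the per-residue feature catalog: for each
#' prefix size i (1 <= i <= F), evaluates a cross-validated random forest
#' on the first i ranked catalog features -- each selected feature
#' contributing its column at every window/patch position -- and records
#' the five metrics. The optimal subset is the prefix maximizing MCC, ties
#' resolved toward the smaller subset; prefixes with undefined MCC are
#' never selected.
#'
#' @param ranking A `ppi_mrmr` object (or integer permutation) over the
#'   catalog features of `samples`.
#' @inheritParams cross_validate
#' @return List of class `ppi_ifs`: `curve` (data.frame with columns `i`,
#'   `sensitivity`, `precision`, `specificity`, `accuracy`, `mcc`),
#'   `optimal_i`, `optimal_features` (catalog indices, ranking order).
#' @export
incremental_feature_selection <- function(ranking, samples, y = NULL,
                                          n_trees = 197L, k = 10L,
                                          seed = 1L, stratified = TRUE) {
  d <- as_xy(samples, y)
  ranked <- if (inherits(ranking, "ppi_mrmr")) ranking$feature else
    as.integer(ranking)
  if (!setequal(ranked, seq_len(d$per_dim))) {
    stop("ranking must be a permutation of the ", d$per_dim,
         " catalog features")
  }
  F_total <- length(ranked)
  curve <- data.frame(i = seq_len(F_total), sensitivity = NA_real_,
                      precision = NA_real_, specificity = NA_real_,
                      accuracy = NA_real_, mcc = NA_real_)
  for (i in seq_len(F_total)) {
    cols <- expand_feature_columns(ranked[seq_len(i)], d$width, d$per_dim)
    cv <- cross_validate(d$X[, cols, drop = FALSE], d$y, n_trees = n_trees,
                         k = k, seed = seed, stratified = stratified)
    m <- cv$metrics
    curve[i, -1L] <- as.numeric(m[c("sensitivity", "precision",
                                    "specificity", "accuracy", "mcc")])
  }
  mcc <- curve$mcc
  if (all(is.na(mcc))) stop("MCC undefined for every subset size")
  optimal_i <- which.max(ifelse(is.na(mcc), -Inf, mcc))  # ties -> smallest i
  structure(list(curve = curve, optimal_i = optimal_i,
                 optimal_features = ranked[seq_len(optimal_i)]),
            class = "ppi_ifs")
}

#' @export
print.ppi_ifs <- function(x, ...) {
  cat("ppi_ifs: curve over", nrow(x$curve), "subset sizes; optimal i =",
      x$optimal_i, "(MCC =", round(x$curve$mcc[x$optimal_i], 4), ")\n")
  invisible(x)
}

#' Repeated balanced undersampling evaluation
#'
#' Counteracts class imbalance: in each of `repeats` rounds, all positive
#' samples are combined with an equally sized, seeded, without-replacement
#' draw of negatives; the balanced subset is cross-validated; and the
#' final result is the arithmetic mean of each metric over the rounds.
#'
#' @inheritParams cross_validate
#' @param repeats Number of balanced resampling rounds (default 100).
#' @return List of class `ppi_balanced`: `metrics` (mean over repeats),
#'   `per_repeat` (data.frame of the five metrics per round), `draws`
#'   (list of negative-sample index draws).
#' @export
balanced_ensemble_evaluate <- function(samples, y = NULL, n_trees = 197L,
                                       k = 10L, repeats = 100L, seed = 1L,
                                       stratified = TRUE) {
  d <- as_xy(samples, y)
  if (repeats < 1L) stop("repeats must be >= 1")
  pos <- which(d$y == 1L)
  neg <- which(d$y == 0L)
  if (!length(pos)) stop("degenerate data: no positive samples")
  if (length(pos) > length(neg)) {
    stop("positives exceed negatives; balanced undersampling expects ",
         "positives <= negatives")
  }
  per_repeat <- data.frame(repeat_id = seq_len(repeats),
                           sensitivity = NA_real_, precision = NA_real_,
                           specificity = NA_real_, accuracy = NA_real_,
                           mcc = NA_real_)
  draws <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    draw <- withr::with_seed(seed + r, sample(neg, length(pos)))
    draws[[r]] <- draw
    idx <- c(pos, draw)
    cv <- cross_validate(d$X[idx, , drop = FALSE], d$y[idx],
                         n_trees = n_trees, k = k, seed = seed + r,
                         stratified = stratified)
    per_repeat[r, -1L] <- as.numeric(
      cv$metrics[c("sensitivity", "precision", "specificity",
                   "accuracy", "mcc")])
  }
  metrics <- colMeans(per_repeat[, -1L])
  structure(list(metrics = metrics, per_repeat = per_repeat, draws = draws,
                 repeats = repeats, seed = seed),
            class = "ppi_balanced")
}

#' Write an IFS curve as TSV
#'
#' @param ifs A `ppi_ifs` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ifs_tsv <- function(ifs, path) {
  utils::write.table(ifs$curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
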