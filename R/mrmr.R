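# Minimum-redundancy maximum-relevance feature ranking from first
# principles: plug-in mutual information on 3-level discretized features,
# greedy selection by the difference (MID) or quotient (MIQ) criterion.

#' Three-level feature discretization
#'
#' Bins a continuous feature into `{-1, 0, +1}` at mean +/- alpha * sd:
#' values at or below the lower threshold map to -1, at or above the upper
#' to +1, the rest to 0. The sd is the population standard deviation and
#' the thresholds are inclusive, so a balanced 0/1 vector (mean 0.5,
#' population sd exactly 0.5) discretizes to -1/+1 rather than collapsing
#' to the middle bin. A constant feature (sd = 0) maps entirely to 0.
#' This is the conventional preprocessing of the classic mRMR program.
#'
#' @param x Numeric vector (finite values).
#' @param alpha Threshold width in standard deviations (default 1).
#' @return Integer vector over `{-1, 0, 1}`.
#' @export
discretize <- function(x, alpha = 1) {
  if (!all(is.finite(x))) stop("discretize: values must be finite")
  if (alpha < 0) stop("alpha must be >= 0")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))   # population sd
  if (length(x) < 2L || is.na(s) || s == 0) return(rep(0L, length(x)))
  out <- integer(length(x))
  out[x <= m - alpha * s] <- -1L
  out[x >= m + alpha * s] <- 1L
  out
}

#' Mutual information of two discrete vectors
#'
#' Plug-in estimate in bits: I(X;Y) = sum over observed cells of
#' p(x,y) log2( p(x,y) / (p(x) p(y)) ), with 0 log 0 = 0 and empirical
#' cell probabilities.
#'
#' @param x,y Discrete vectors (integer, character or factor) of equal
#'   length.
#' @return Non-negative mutual information in bits.
#' @examples
#' mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1))  # 1 bit
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) {
    stop("mutual_information: vectors differ in length (",
         length(x), " vs ", length(y), ")")
  }
  if (!length(x)) stop("mutual_information: empty vectors")
  tab <- table(x, y)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  ratio <- p / outer(px, py)
  # clamp tiny negative rounding away; plug-in MI is >= 0 in exact arithmetic
  max(0, sum(p[nz] * log2(ratio[nz])))
}

#' @keywords internal
shannon_entropy <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Relevance of a feature to the class
#'
#' D = I(f; c): mutual information between the (discretized) feature and
#' the class labels.
#'
#' @param feature Numeric feature vector (discretized internally) or an
#'   already-discrete integer vector when `discretized = TRUE`.
#' @param class_labels Binary class vector.
#' @param alpha Discretization width (see [discretize()]).
#' @param discretized Set `TRUE` if `feature` is already discrete.
#' @return Relevance in bits.
#' @export
relevance <- function(feature, class_labels, alpha = 1, discretized = FALSE) {
  f <- if (discretized) feature else discretize(feature, alpha)
  mutual_information(f, class_labels)
}

#' Redundancy of a feature against a selected set
#'
#' R = (1/m) * sum over selected features f_i of I(f; f_i). An empty
#' selected set has redundancy 0 (the first greedy pick is by relevance
#' alone).
#'
#' @param feature Numeric (or discrete) feature vector.
#' @param selected Matrix whose columns are the already-selected features
#'   (may have zero columns).
#' @inheritParams relevance
#' @return Mean mutual information in bits.
#' @export
redundancy <- function(feature, selected, alpha = 1, discretized = FALSE) {
  selected <- as.matrix(selected)
  if (ncol(selected) == 0L) return(0)
  f <- if (discretized) feature else discretize(feature, alpha)
  mis <- vapply(seq_len(ncol(selected)), function(j) {
    g <- if (discretized) selected[, j] else discretize(selected[, j], alpha)
    mutual_information(f, g)
  }, numeric(1))
  mean(mis)
}

#' mRMR feature ranking
#'
#' Greedy minimum-redundancy maximum-relevance ordering of all features.
#' The first pick maximizes relevance D = I(f; c); each subsequent pick
#' maximizes D - R (MID, the difference criterion) or D / R (MIQ, the
#' quotient criterion with R guarded below by `eps`), where R is the mean
#' mutual information with the already-selected set. Criterion ties are
#' broken toward the lower feature index, so the ranking is deterministic.
#'
#' @param X Numeric sample-by-feature matrix (>= 2 features).
#' @param y Binary class labels, one per row of `X`.
#' @param scheme `"MID"` (default) or `"MIQ"`.
#' @param alpha Discretization width (see [discretize()]).
#' @param eps Lower guard on R for the MIQ quotient (default 1e-12).
#' @return Object of class `ppi_mrmr`: a data.frame with columns `rank`,
#'   `feature` (column index), `name`, `criterion`, `relevance`,
#'   `redundancy`, plus attributes `scheme` and `alpha`.
#' @examples
#' set.seed(1)
#' y <- rep(0:1, each = 50)
#' X <- cbind(sig = y + rnorm(100, sd = 0.3), noise = rnorm(100))
#' mrmr_rank(X, y)
#' @export
mrmr_rank <- function(X, y, scheme = c("MID", "MIQ"), alpha = 1,
                      eps = 1e-12) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("mrmr_rank needs at least 2 features")
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (length(unique(y)) != 2L) stop("class labels must be binary")
  p <- ncol(X)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("f", sprintf("%04d", seq_len(p)))

  D <- apply(X, 2, discretize, alpha = alpha)
  rel <- vapply(seq_len(p), function(j) mutual_information(D[, j], y),
                numeric(1))

  order_out <- integer(p)
  crit_out <- red_out <- numeric(p)
  candidates <- seq_len(p)           # kept ascending for the tie rule
  redsum <- numeric(p)               # sum of MI with selected features

  pick <- candidates[which.max(rel[candidates])]
  order_out[1L] <- pick
  crit_out[1L] <- rel[pick]
  red_out[1L] <- 0
  candidates <- setdiff(candidates, pick)

  for (step in seq_len(p - 1L)) {
    last <- order_out[step]
    for (j in candidates) {
      redsum[j] <- redsum[j] + mutual_information(D[, j], D[, last])
    }
    m <- step
    red <- redsum[candidates] / m
    crit <- if (scheme == "MID") {
      rel[candidates] - red
    } else {
      rel[candidates] / pmax(red, eps)
    }
    k <- which.max(crit)             # ties -> first, i.e. lowest index
    pick <- candidates[k]
    order_out[step + 1L] <- pick
    crit_out[step + 1L] <- crit[k]
    red_out[step + 1L] <- red[k]
    candidates <- candidates[-k]
  }

  out <- data.frame(rank = seq_len(p), feature = order_out,
                    name = nm[order_out], criterion = crit_out,
                    relevance = rel[order_out], redundancy = red_out,
                    stringsAsFactors = FALSE)
  attr(out, "scheme") <- scheme
  attr(out, "alpha") <- alpha
  class(out) <- c("ppi_mrmr", "data.frame")
  out
}

#' Write an mRMR ranking as TSV
#'
#' @param ranking A `ppi_mrmr` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
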