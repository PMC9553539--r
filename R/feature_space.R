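# Feature-space constructions: one classification sample per surface
# residue, encoded as a single residue, a sliding sequence window, or a
# spatial patch of nearest residues.

#' @keywords internal
new_ppi_samples <- function(X, y, centers, width, per_dim, mode) {
  stopifnot(nrow(X) == length(y), ncol(X) == width * per_dim)
  structure(list(X = X, y = as.integer(y), centers = centers,
                 width = width, per_dim = per_dim, mode = mode),
            class = "ppi_samples")
}

#' @export
print.ppi_samples <- function(x, ...) {
  cat("ppi_samples (", x$mode, "): ", nrow(x$X), " samples x ", ncol(x$X),
      " features (width ", x$width, " x ", x$per_dim, " per residue), ",
      sum(x$y == 1L), " positive\n", sep = "")
  invisible(x)
}

#' @keywords internal
position_colnames <- function(feature_names, width) {
  if (width == 1L) return(feature_names)
  as.vector(vapply(seq_len(width), function(p) {
    paste0("p", sprintf("%02d", p), "_", feature_names)
  }, character(length(feature_names))))
}

#' Single-residue samples
#'
#' One sample per surface residue, carrying only that residue's feature
#' vector. Non-surface residues are never sample centers.
#'
#' @param features L x D numeric matrix of per-residue feature vectors.
#' @param labels Binary (0/1 or logical) interface labels, length L.
#' @param surface Logical surface flags, length L.
#' @param centers Optional data.frame of residue identifiers (e.g. columns
#'   `chain`, `resno`), length-L rows; subset to the sample centers.
#' @return A `ppi_samples` object with `width = 1`.
#' @export
single_samples <- function(features, labels, surface, centers = NULL) {
  features <- as.matrix(features)
  L <- nrow(features)
  stopifnot(length(labels) == L, length(surface) == L)
  idx <- which(as.logical(surface))
  if (is.null(centers)) centers <- data.frame(index = seq_len(L))
  X <- features[idx, , drop = FALSE]
  rownames(X) <- NULL
  new_ppi_samples(X, as.integer(labels[idx]),
                  centers[idx, , drop = FALSE],
                  width = 1L, per_dim = ncol(features), mode = "single")
}

#' Sliding-window samples
#'
#' One sample per surface residue: the concatenated feature vectors of the
#' 2n+1 sequence positions centered on it (n upstream, n downstream).
#' Positions falling outside the chain are padded with the all-zero
#' encoding of the null residue `X`. The sample label is the center
#' residue's label.
#'
#' @inheritParams single_samples
#' @param n Window half-width (1 <= n <= 19); full width N = 2n+1.
#' @return A `ppi_samples` object with `width = 2n+1`.
#' @export
window_samples <- function(features, labels, surface, n, centers = NULL) {
  if (n < 1L || n > 19L) stop("window half-width n must be in [1, 19]")
  features <- as.matrix(features)
  L <- nrow(features)
  D <- ncol(features)
  stopifnot(length(labels) == L, length(surface) == L)
  idx <- which(as.logical(surface))
  if (is.null(centers)) centers <- data.frame(index = seq_len(L))
  width <- 2L * n + 1L
  X <- matrix(0, length(idx), width * D)
  for (s in seq_along(idx)) {
    pos <- idx[s] + (-n):n
    inside <- pos >= 1L & pos <= L
    block <- matrix(0, width, D)
    block[inside, ] <- features[pos[inside], , drop = FALSE]
    X[s, ] <- as.vector(t(block))
  }
  fn <- colnames(features)
  if (is.null(fn)) fn <- paste0("f", sprintf("%03d", seq_len(D)))
  colnames(X) <- position_colnames(fn, width)
  new_ppi_samples(X, as.integer(labels[idx]),
                  centers[idx, , drop = FALSE],
                  width = width, per_dim = D, mode = "window")
}

#' Spatial-patch samples
#'
#' One sample per surface residue: the feature vectors of the center plus
#' its m-1 nearest residues in 3D space (Euclidean distance between
#' representative atoms, any chain of the structure). Patch members are
#' ordered center first, then by ascending distance, ties broken by
#' (chain, residue number); members need not be surface residues, only the
#' center must be.
#'
#' @inheritParams single_samples
#' @param coords L x 3 matrix of representative-atom coordinates (Angstrom).
#' @param m Patch size (center included). The study range is 10 <= m <= 25;
#'   values outside it are accepted with a warning.
#' @param chain,resno Optional chain ids and residue numbers (length L)
#'   used for deterministic tie-breaking; default to a single chain and
#'   positional numbering.
#' @return A `ppi_samples` object with `width = m` and the patch membership
#'   in attribute `"members"` (list of row-index vectors).
#' @export
patch_samples <- function(features, labels, surface, coords, m,
                          chain = NULL, resno = NULL, centers = NULL) {
  features <- as.matrix(features)
  coords <- as.matrix(coords)
  L <- nrow(features)
  D <- ncol(features)
  stopifnot(length(labels) == L, length(surface) == L, nrow(coords) == L,
            ncol(coords) == 3L)
  if (m < 1L) stop("patch size m must be >= 1")
  if (m < 10L || m > 25L) {
    if (m != 1L)  # m = 1 is the documented degenerate single-residue case
      warning("patch size m = ", m, " is outside the usual range [10, 25]")
  }
  if (L < m) {
    stop("structure has ", L, " residues but patches need at least ", m)
  }
  if (is.null(chain)) chain <- rep("A", L)
  if (is.null(resno)) resno <- seq_len(L)
  if (is.null(centers)) centers <- data.frame(chain = chain, resno = resno)
  idx <- which(as.logical(surface))
  X <- matrix(0, length(idx), m * D)
  members <- vector("list", length(idx))
  for (s in seq_along(idx)) {
    c0 <- idx[s]
    d2 <- (coords[, 1] - coords[c0, 1])^2 +
          (coords[, 2] - coords[c0, 2])^2 +
          (coords[, 3] - coords[c0, 3])^2
    others <- setdiff(seq_len(L), c0)
    ord <- others[order(d2[others], chain[others], resno[others])]
    sel <- c(c0, ord[seq_len(m - 1L)])
    members[[s]] <- sel
    X[s, ] <- as.vector(t(features[sel, , drop = FALSE]))
  }
  fn <- colnames(features)
  if (is.null(fn)) fn <- paste0("f", sprintf("%03d", seq_len(D)))
  colnames(X) <- position_colnames(fn, m)
  out <- new_ppi_samples(X, as.integer(labels[idx]),
                         centers[idx, , drop = FALSE],
                         width = as.integer(m), per_dim = D, mode = "patch")
  attr(out, "members") <- members
  out
}

#' Write samples as TSV
#'
#' Serializes a `ppi_samples` object as a tab-separated table: identifier
#' columns, feature columns `f0001..fNNNN`, and the binary `label` column.
#' A leading comment line records the window/patch geometry so
#' [read_samples_tsv()] can reconstruct the object.
#'
#' @param samples A `ppi_samples` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_samples_tsv <- function(samples, path) {
  stopifnot(inherits(samples, "ppi_samples"))
  X <- samples$X
  colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
  df <- cbind(samples$centers, as.data.frame(X), label = samples$y)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ppisite_samples mode=%s width=%d per_dim=%d id_cols=%d",
                     samples$mode, samples$width, samples$per_dim,
                     ncol(samples$centers)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read samples from TSV
#'
#' @param path Path written by [write_samples_tsv()].
#' @return A `ppi_samples` object.
#' @export
read_samples_tsv <- function(path) {
  if (!file.exists(path)) stop("cannot read samples file: ", path)
  header <- readLines(path, n = 1L)
  meta <- list(mode = "single", width = 1L, per_dim = NA_integer_, id_cols = 0L)
  if (startsWith(header, "# ppisite_samples")) {
    kv <- regmatches(header, gregexpr("[a-z_]+=[^ ]+", header))[[1]]
    for (pair in kv) {
      p <- strsplit(pair, "=", fixed = TRUE)[[1]]
      meta[[p[1]]] <- if (p[1] == "mode") p[2] else as.integer(p[2])
    }
  }
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  fcols <- grep("^f[0-9]+$", names(df))
  lab <- df$label
  idc <- setdiff(seq_along(df), c(fcols, match("label", names(df))))
  X <- as.matrix(df[, fcols, drop = FALSE])
  if (is.na(meta$per_dim)) meta$per_dim <- ncol(X)
  new_ppi_samples(X, lab, df[, idc, drop = FALSE],
                  width = meta$width, per_dim = meta$per_dim,
                  mode = meta$mode)
}
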