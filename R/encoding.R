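# Per-residue feature encoding: Atchley factors, PSSM conservation scores,
# secondary-structure one-hot, disorder, and the 3D structural block.

#' @keywords internal
check_aa <- function(aa, allow_x = TRUE) {
  aa <- toupper(aa)
  ok <- aa %in% AA1 | (allow_x & aa == "X")
  if (any(!ok)) {
    stop("invalid amino-acid symbol(s): ",
         paste(unique(aa[!ok]), collapse = ", "))
  }
  aa
}

#' Atchley factor encoding
#'
#' Maps amino acids to the five Atchley factor scores (polarity,
#' secondary-structure propensity, molecular size, codon composition,
#' electrostatic charge). The padding symbol `"X"` encodes as five zeros.
#'
#' @param aa Character vector of one-letter codes (case-insensitive).
#' @return Numeric matrix, `length(aa)` x 5, columns `atchley_f1..f5`.
#' @examples
#' encode_atchley(c("A", "X"))
#' @export
encode_atchley <- function(aa) {
  aa <- check_aa(aa)
  out <- matrix(0, length(aa), 5,
                dimnames = list(NULL, colnames(ATCHLEY)))
  std <- aa != "X"
  out[std, ] <- ATCHLEY[aa[std], , drop = FALSE]
  out
}

#' Kyte-Doolittle hydropathy
#'
#' @param aa Character vector of one-letter codes; `"X"` maps to 0.
#' @return Numeric vector of hydropathy values.
#' @examples
#' kyte_doolittle(c("I", "R"))
#' @export
kyte_doolittle <- function(aa) {
  aa <- check_aa(aa)
  out <- numeric(length(aa))
  std <- aa != "X"
  out[std] <- unname(KD_SCALE[aa[std]])
  out
}

#' Secondary-structure one-hot encoding
#'
#' Encodes three-state secondary structure as a binary triple:
#' strand `E` -> (1,0,0), helix `H` -> (0,1,0), other `C` -> (0,0,1).
#'
#' @param ss Character vector over `{E, H, C}`.
#' @return Integer matrix, `length(ss)` x 3, columns `ss_E`, `ss_H`, `ss_C`.
#' @export
encode_secondary_structure <- function(ss) {
  ss <- toupper(ss)
  bad <- !(ss %in% c("E", "H", "C"))
  if (any(bad)) {
    stop("invalid secondary-structure symbol(s): ",
         paste(unique(ss[bad]), collapse = ", "))
  }
  out <- matrix(0L, length(ss), 3, dimnames = list(NULL, c("ss_E", "ss_H", "ss_C")))
  out[cbind(seq_along(ss), match(ss, c("E", "H", "C")))] <- 1L
  out
}

#' Read a PSI-BLAST ASCII PSSM profile
#'
#' Parses the ASCII matrix PSI-BLAST writes (`-Q` output): two header lines,
#' then one row per residue with position, amino acid, 20 log-odds columns
#' (order `ARNDCQEGHILKMFPSTWYV`) followed by percentage columns, ending at
#' the footer statistics.
#'
#' @param path Path to the PSSM file.
#' @return List of class `pssm`: `sequence` (one-letter string) and
#'   `scores` (L x 20 integer matrix, columns named by amino acid).
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) stop("cannot read PSSM file: ", path)
  lines <- readLines(path, warn = FALSE)
  seq_aa <- character()
  rows <- list()
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 22L) next
    if (is.na(suppressWarnings(as.integer(tok[1L])))) next
    if (!(toupper(tok[2L]) %in% c(AA1, "X", "B", "Z", "U", "O"))) next
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(vals)) {
      stop("malformed PSSM row at position ", tok[1L], " in '", path, "'")
    }
    seq_aa <- c(seq_aa, toupper(tok[2L]))
    rows[[length(rows) + 1L]] <- vals
  }
  if (!length(rows)) stop("no PSSM rows found in '", path, "'")
  scores <- do.call(rbind, rows)
  colnames(scores) <- PSSM_COLS
  structure(list(sequence = paste(seq_aa, collapse = ""), scores = scores),
            class = "pssm")
}

#' Assemble the per-residue feature vector
#'
#' Concatenates the five feature blocks in fixed order
#' `[Atchley:5 | PSSM:20 | SS:3 | disorder:1 | struct:K]`; with the default
#' 11-column structural block this is the 40-component residue encoding.
#' The padding residue `"X"` takes all-zero Atchley/PSSM/SS blocks.
#'
#' @param aa One-letter amino-acid code (or `"X"` for padding).
#' @param pssm_row Numeric vector of 20 PSSM log-odds scores.
#' @param ss_char Secondary-structure symbol in `{E, H, C}`, or `NA` for
#'   padding (encoded as three zeros).
#' @param disorder Disorder score in `[0, 1]`.
#' @param struct_row Named numeric vector for the 3D structural block.
#' @return Named numeric feature vector of length `29 + length(struct_row)`.
#' @examples
#' v <- assemble_features("A", rep(0, 20), "H", 0.2,
#'                        stats::setNames(rep(0, 11), ppisite_struct_cols()))
#' length(v)
#' @export
assemble_features <- function(aa, pssm_row, ss_char, disorder, struct_row) {
  if (length(pssm_row) != 20L) {
    stop("PSSM block must have 20 columns, got ", length(pssm_row))
  }
  if (length(disorder) != 1L || is.na(disorder) ||
      disorder < 0 || disorder > 1) {
    stop("disorder score must be a single value in [0, 1]")
  }
  ss_block <- if (is.na(ss_char)) {
    stats::setNames(rep(0L, 3), c("ss_E", "ss_H", "ss_C"))
  } else {
    drop(encode_secondary_structure(ss_char))
  }
  sr <- as.numeric(struct_row)
  names(sr) <- if (is.null(names(struct_row))) {
    paste0("struct_", seq_along(sr))
  } else {
    names(struct_row)
  }
  pr <- as.numeric(pssm_row)
  names(pr) <- paste0("pssm_", PSSM_COLS)
  c(drop(encode_atchley(aa)), pr, ss_block,
    disorder = as.numeric(disorder), sr)
}

#' Default names of the 3D structural descriptor block
#'
#' @return Character vector of the 11 default structural column names.
#' @export
ppisite_struct_cols <- function() STRUCT_COLS

#' Encode every residue of a chain
#'
#' Vectorized assembly of the per-residue feature matrix for a chain, from
#' its sequence and the four feature tracks.
#'
#' @param sequence One-letter amino-acid string (or character vector), length L.
#' @param pssm A `pssm` object (see [read_pssm()]) or an L x 20 matrix.
#' @param ss Secondary-structure string/vector over `{E,H,C}`, length L.
#' @param disorder Numeric vector in `[0,1]`, length L.
#' @param struct L x K numeric matrix or data.frame of 3D descriptors
#'   (default column layout from [ppisite_struct_cols()]).
#' @return L x (29 + K) numeric matrix; rows are residues.
#' @export
featurize_chain <- function(sequence, pssm, ss, disorder, struct) {
  aa <- if (length(sequence) == 1L && nchar(sequence[1L]) > 1L) {
    strsplit(sequence, "")[[1]]
  } else {
    as.character(sequence)
  }
  L <- length(aa)
  scores <- if (inherits(pssm, "pssm")) pssm$scores else as.matrix(pssm)
  ssv <- if (length(ss) == 1L && nchar(ss[1L]) > 1L) {
    strsplit(ss, "")[[1]]
  } else {
    as.character(ss)
  }
  struct <- as.matrix(struct)
  if (nrow(scores) != L || length(ssv) != L || length(disorder) != L ||
      nrow(struct) != L) {
    stop("feature tracks disagree on chain length (expected ", L, " rows)")
  }
  if (any(disorder < 0 | disorder > 1)) {
    stop("disorder scores must lie in [0, 1]")
  }
  if (is.null(colnames(struct))) {
    colnames(struct) <- paste0("struct_", seq_len(ncol(struct)))
  }
  out <- cbind(encode_atchley(aa),
               `colnames<-`(scores, paste0("pssm_", PSSM_COLS)),
               encode_secondary_structure(ssv),
               disorder = as.numeric(disorder),
               struct)
  rownames(out) <- NULL
  out
}

#' Read a per-residue feature track from TSV
#'
#' Reads a tab-separated table with a header row and one row per residue,
#' as written by external descriptor programs.
#'
#' @param path Path to the TSV file.
#' @return data.frame of the track.
#' @export
read_track_tsv <- function(path) {
  if (!file.exists(path)) stop("cannot read track file: ", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
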