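# Fixture builders: toy PDB files and PSSM profiles generated in code.

# Write a PDB file with one single-atom residue per coordinate row.
toy_pdb_file <- function(coords, elety = "C", element = "C", chain = "A",
                         aa3 = "GLY", path = tempfile(fileext = ".pdb")) {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  elety <- rep_len(elety, n)
  element <- rep_len(element, n)
  chain <- rep_len(chain, n)
  aa3 <- rep_len(aa3, n)
  name4 <- ifelse(nchar(elety) < 4L, sprintf(" %-3s", elety), elety)
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(n), name4, aa3, chain, seq_len(n),
    coords[, 1], coords[, 2], coords[, 3], 1.00, 0.00, element)
  writeLines(c(lines, "END"), path)
  path
}

# Structure object from bare coordinates (single-atom residues).
toy_structure <- function(coords, ...) {
  read_pdb_structure(toy_pdb_file(coords, ...))
}

hetatm_only_pdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- sprintf(
    "HETATM%5d  O   HOH %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
    1:3, "A", 1:3, c(0, 3, 6), 0, 0, 1.00, 0.00)
  writeLines(c(lines, "END"), path)
  path
}

# PSI-BLAST ASCII PSSM fixture: residue i scores +9 for its own column,
# -1 elsewhere; percentage columns all zero.
pssm_fixture_file <- function(sequence = "ARNDCQE",
                              path = tempfile(fileext = ".pssm")) {
  aas <- strsplit(sequence, "")[[1]]
  cols <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  hdr1 <- "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapped real matches to pseudocounts"
  hdr2 <- paste0("           ", paste(sprintf("%3s", c(cols, cols)),
                                      collapse = " "))
  rows <- vapply(seq_along(aas), function(i) {
    scores <- rep(-1L, 20)
    scores[match(aas[i], cols)] <- 9L
    paste0(sprintf("%5d %s  ", i, aas[i]),
           paste(sprintf("%3d", c(scores, rep(0L, 20))), collapse = " "),
           "  0.30 0.09")
  }, character(1))
  writeLines(c(hdr1, hdr2, rows, "", "                      K         Lambda"),
             path)
  path
}

# Per-residue feature matrix with the default 40-column layout, filled
# with deterministic values, for feature-space construction tests.
toy_feature_matrix <- function(L, D = 40L) {
  m <- matrix(seq_len(L * D) / 100, L, D)
  colnames(m) <- if (D == 40L) residue_feature_names() else
    sprintf("f%03d", seq_len(D))
  m
}
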