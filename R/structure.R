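# Structure handling: PDB input, Shrake-Rupley accessibility, and the
# surface / interface labeling rules.

#' Read a PDB structure into a residue-level model
#'
#' Parses the ATOM records of a PDB file (via [bio3d::read.pdb()]) into a
#' light residue-level structure object. HETATM records (including waters)
#' are excluded, hydrogens are dropped (united-atom convention), alternate
#' locations are resolved to the highest-occupancy conformer, and only the
#' first model of multi-model files is used.
#'
#' @param path Path to a PDB file containing at least one ATOM record.
#' @return An object of class `ppi_structure`: a list with
#'   \describe{
#'     \item{atoms}{data.frame with one row per heavy atom: `chain`, `resno`,
#'       `icode`, `aa` (one-letter, `"X"` for nonstandard), `elety` (atom
#'       name), `element`, `x`, `y`, `z`, `radius` (van der Waals, Angstrom),
#'       `res_index` (1-based index into `residues`).}
#'     \item{residues}{data.frame with one row per residue: `chain`, `resno`,
#'       `icode`, `aa`, and the representative coordinate `rep_x/rep_y/rep_z`
#'       (the C-alpha atom if present, otherwise the atom centroid).}
#'   }
#' @examples
#' pdb <- simulate_dimer(n_residues = 6, seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' write_pdb_structure(pdb$structure, f)
#' s <- read_pdb_structure(f)
#' nrow(s$residues)
#' @export
read_pdb_structure <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read PDB file: ", path)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) {
    stop("empty structure: no ATOM records in '", path, "'")
  }
  element <- toupper(trimws(at$elesy))
  missing_el <- is.na(element) | element == ""
  if (any(missing_el)) {
    # fall back on the first alphabetic character of the atom name
    element[missing_el] <- substr(gsub("[^A-Za-z].*", "",
                                       gsub("^[^A-Za-z]*", "",
                                            at$elety[missing_el])), 1, 1)
    element[missing_el] <- toupper(element[missing_el])
  }
  keep <- !(element %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  element <- element[keep]
  if (nrow(at) == 0L) {
    stop("empty structure: only hydrogen atoms in '", path, "'")
  }

  icode <- ifelse(is.na(at$insert), "", at$insert)
  # alternate locations: keep the highest-occupancy copy of each atom
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  atom_key <- paste(at$chain, at$resno, icode, at$elety, sep = "\r")
  if (anyDuplicated(atom_key)) {
    ord <- order(atom_key, -occ)
    first <- !duplicated(atom_key[ord])
    keep_rows <- sort(seq_len(nrow(at))[ord][first])
    at <- at[keep_rows, , drop = FALSE]
    element <- element[keep_rows]
    icode <- icode[keep_rows]
  }

  aa <- unname(AA3[at$resid])
  aa[is.na(aa)] <- "X"
  radius <- unname(VDW_RADII[element])
  radius[is.na(radius)] <- VDW_DEFAULT

  res_key <- paste(at$chain, at$resno, icode, sep = "\r")
  res_index <- match(res_key, unique(res_key))  # file order preserved

  atoms <- data.frame(
    chain = at$chain, resno = at$resno, icode = icode, aa = aa,
    elety = at$elety, element = element,
    x = at$x, y = at$y, z = at$z, radius = radius,
    res_index = res_index, stringsAsFactors = FALSE
  )
  new_ppi_structure(atoms)
}

#' @keywords internal
new_ppi_structure <- function(atoms) {
  stopifnot(nrow(atoms) > 0L, all(atoms$radius > 0),
            all(is.finite(c(atoms$x, atoms$y, atoms$z))))
  idx <- atoms$res_index
  first <- !duplicated(idx)
  n_res <- max(idx)
  rep_xyz <- matrix(NA_real_, n_res, 3)
  for (i in seq_len(n_res)) {
    sel <- which(idx == i)
    ca <- sel[atoms$elety[sel] == "CA"]
    if (length(ca) >= 1L) {
      rep_xyz[i, ] <- c(atoms$x[ca[1L]], atoms$y[ca[1L]], atoms$z[ca[1L]])
    } else {
      rep_xyz[i, ] <- c(mean(atoms$x[sel]), mean(atoms$y[sel]),
                        mean(atoms$z[sel]))
    }
  }
  residues <- data.frame(
    chain = atoms$chain[first], resno = atoms$resno[first],
    icode = atoms$icode[first], aa = atoms$aa[first],
    rep_x = rep_xyz[, 1], rep_y = rep_xyz[, 2], rep_z = rep_xyz[, 3],
    stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms, residues = residues), class = "ppi_structure")
}

#' @export
print.ppi_structure <- function(x, ...) {
  cat("ppi_structure:", nrow(x$residues), "residues,", nrow(x$atoms),
      "atoms,", length(unique(x$residues$chain)), "chain(s)\n")
  invisible(x)
}

#' Extract one chain of a structure as a standalone monomer
#'
#' @param structure A `ppi_structure`.
#' @param chain Chain identifier.
#' @return A `ppi_structure` containing only that chain.
#' @export
chain_structure <- function(structure, chain) {
  stopifnot(inherits(structure, "ppi_structure"))
  atoms <- structure$atoms[structure$atoms$chain == chain, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no such chain: ", chain)
  atoms$res_index <- match(atoms$res_index, unique(atoms$res_index))
  new_ppi_structure(atoms)
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
#' @keywords internal
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Computes per-residue solvent-accessible surface area (ASA) by rolling a
#' probe sphere over the heavy atoms: each atom is surrounded by a
#' quasi-uniform lattice of test points at radius (vdW + probe); the
#' accessible fraction (points not buried inside any neighbouring expanded
#' sphere) times the expanded sphere area is the atom ASA, and residue ASA
#' is the sum over its atoms.
#'
#' @param structure A `ppi_structure`.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4, water).
#' @param n_points Test points per atom (default 960; must be >= 100).
#'   Larger values converge to the exact area at O(1/n) cost.
#' @return Numeric vector of residue ASA values (Angstrom^2) in residue
#'   order, with the per-atom values in attribute `"atom_asa"`.
#' @examples
#' d <- simulate_dimer(n_residues = 6, seed = 1)
#' asa <- shrake_rupley(d$structure)
#' head(asa)
#' @export
shrake_rupley <- function(structure, probe_radius = 1.4, n_points = 960L) {
  stopifnot(inherits(structure, "ppi_structure"))
  if (n_points < 100L) stop("n_points must be >= 100")
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  atoms <- structure$atoms
  nat <- nrow(atoms)
  coords <- cbind(atoms$x, atoms$y, atoms$z)
  radii <- atoms$radius + probe_radius
  sph <- fibonacci_sphere(n_points)

  atom_asa <- numeric(nat)
  if (nat == 1L) {
    atom_asa[1L] <- 4 * pi * radii[1L]^2
  } else {
    d2 <- as.matrix(stats::dist(coords))^2
    for (i in seq_len(nat)) {
      nb <- which(d2[i, ] < (radii[i] + radii)^2)
      nb <- nb[nb != i]
      acc <- rep(TRUE, n_points)
      if (length(nb)) {
        pts <- sph * radii[i]
        pts[, 1] <- pts[, 1] + coords[i, 1]
        pts[, 2] <- pts[, 2] + coords[i, 2]
        pts[, 3] <- pts[, 3] + coords[i, 3]
        # test the closest occluders first so points die early
        for (j in nb[order(d2[i, nb])]) {
          sel <- which(acc)
          if (!length(sel)) break
          dx <- pts[sel, 1] - coords[j, 1]
          dy <- pts[sel, 2] - coords[j, 2]
          dz <- pts[sel, 3] - coords[j, 3]
          acc[sel] <- dx * dx + dy * dy + dz * dz > radii[j]^2
        }
      }
      atom_asa[i] <- 4 * pi * radii[i]^2 * sum(acc) / n_points
    }
  }
  res_asa <- as.numeric(tapply(atom_asa, atoms$res_index, sum))
  attr(res_asa, "atom_asa") <- atom_asa
  res_asa
}

#' Relative solvent accessibility
#'
#' Divides a residue ASA by the theoretical maximum accessibility of its
#' amino-acid type (Tien et al. 2013 reference values).
#'
#' @param asa Residue ASA in Angstrom^2 (vectorized).
#' @param aa One-letter amino-acid code(s); must be one of the 20 standard
#'   residues (no reference value exists for `"X"`).
#' @return Relative accessibility (dimensionless, >= 0).
#' @export
relative_asa <- function(asa, aa) {
  stopifnot(length(asa) == length(aa))
  aa <- toupper(aa)
  bad <- !(aa %in% names(MAX_ASA))
  if (any(bad)) {
    stop("no max-ASA reference for residue type(s): ",
         paste(unique(aa[bad]), collapse = ", "))
  }
  as.numeric(asa) / unname(MAX_ASA[aa])
}

#' Surface residue rule
#'
#' A residue is a surface residue when its relative accessibility exceeds
#' the threshold (strictly greater than 25% by default).
#'
#' @param rasa Relative accessibility (vectorized).
#' @param threshold Surface cut-off as a fraction (default 0.25).
#' @return Logical vector.
#' @export
label_surface <- function(rasa, threshold = 0.25) {
  as.numeric(rasa) > threshold
}

#' Interface residue rule
#'
#' A surface residue is an interface residue when complex formation buries
#' at least `delta` of its accessible area: monomer ASA minus complex ASA
#' >= delta. Non-surface residues are never interface residues.
#'
#' @param masa Residue ASA computed on the isolated chain (Angstrom^2).
#' @param casa Residue ASA computed in the full complex (Angstrom^2).
#' @param is_surface Logical surface flag (see [label_surface()]).
#' @param delta Burial threshold in Angstrom^2 (default 1.0).
#' @return Logical vector.
#' @export
label_interface <- function(masa, casa, is_surface, delta = 1.0) {
  stopifnot(length(masa) == length(casa))
  is_surface & ((as.numeric(masa) - as.numeric(casa)) >= delta)
}

#' Label every residue of a complex as surface / interface
#'
#' Runs the full accessibility pipeline: complex ASA (CASA) on the whole
#' assembly, monomer ASA (MASA) by recomputing each chain extracted alone,
#' relative accessibility of the monomer against the max-ASA reference, then
#' the surface (RASA > 25%) and interface (MASA - CASA >= 1 Angstrom^2)
#' rules. Residues of nonstandard type (aa `"X"`) have no reference value;
#' their `rasa` is `NA` and they are never labeled surface.
#'
#' @param structure A `ppi_structure` (typically a multi-chain complex).
#' @param probe_radius,n_points Passed to [shrake_rupley()].
#' @param surface_threshold RASA surface cut-off (default 0.25).
#' @param interface_delta Burial threshold in Angstrom^2 (default 1.0).
#' @return data.frame with one row per residue: `chain`, `resnum`, `icode`,
#'   `aa`, `asa` (ASA in the given assembly, equal to `casa`), `rasa`
#'   (monomer relative accessibility), `masa`, `casa`, `is_surface`,
#'   `is_interface`.
#' @examples
#' d <- simulate_dimer(n_residues = 8, seed = 1)
#' lab <- label_structure(d$structure, n_points = 240)
#' table(lab$is_interface)
#' @export
label_structure <- function(structure, probe_radius = 1.4, n_points = 960L,
                            surface_threshold = 0.25, interface_delta = 1.0) {
  stopifnot(inherits(structure, "ppi_structure"))
  res <- structure$residues
  casa <- as.numeric(shrake_rupley(structure, probe_radius, n_points))
  masa <- numeric(nrow(res))
  for (ch in unique(res$chain)) {
    mono <- chain_structure(structure, ch)
    masa[res$chain == ch] <- as.numeric(
      shrake_rupley(mono, probe_radius, n_points))
  }
  rasa <- rep(NA_real_, nrow(res))
  std <- res$aa %in% names(MAX_ASA)
  rasa[std] <- relative_asa(masa[std], res$aa[std])
  is_surface <- !is.na(rasa) & label_surface(rasa, surface_threshold)
  is_interface <- label_interface(masa, casa, is_surface, interface_delta)
  data.frame(
    chain = res$chain, resnum = res$resno, icode = res$icode, aa = res$aa,
    asa = casa, rasa = rasa, masa = masa, casa = casa,
    is_surface = is_surface, is_interface = is_interface,
    stringsAsFactors = FALSE
  )
}

#' Write a residue label table as TSV
#'
#' @param labels data.frame from [label_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a structure as a minimal PDB file
#'
#' Emits fixed-column ATOM records (wwPDB v3.3 layout) for a
#' `ppi_structure`, so synthetic toy structures round-trip through
#' [read_pdb_structure()].
#'
#' @param structure A `ppi_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_structure <- function(structure, path) {
  stopifnot(inherits(structure, "ppi_structure"))
  at <- structure$atoms
  aa3 <- names(AA3)[match(at$aa, AA3)]
  aa3[is.na(aa3)] <- "UNK"
  name4 <- ifelse(nchar(at$elety) < 4L,
                  sprintf(" %-3s", at$elety), at$elety)
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)), name4, aa3, at$chain, at$resno,
    ifelse(at$icode == "", " ", at$icode),
    at$x, at$y, at$z, 1.00, 0.00, at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
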