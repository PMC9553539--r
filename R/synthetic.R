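# Synthetic data: feature datasets with planted class signal/redundancy at
# a controlled class imbalance, and toy dimer structures with a planted
# contact region, so every pipeline stage is testable without downloads.

#' Names of the default 40-column per-residue feature catalog
#'
#' @return Character vector of 40 feature names in block order
#'   (Atchley, PSSM, secondary structure, disorder, 3D structural).
#' @export
residue_feature_names <- function() {
  c(colnames(ATCHLEY), paste0("pssm_", PSSM_COLS),
    c("ss_E", "ss_H", "ss_C"), "disorder", STRUCT_COLS)
}

#' Simulate a feature dataset with planted signal
#'
#' Generates a sample-by-feature matrix with binary labels at a fixed
#' class imbalance. Informative features are N(0,1) for negatives and
#' N(effect_size, 1) for positives; redundant features are a jittered copy
#' of an informative parent; noise features are N(0,1) independent of the
#' labels. The positive count is fixed at `round(n * positive_fraction)`
#' (not Bernoulli), so balanced-sampling tests are deterministic in shape.
#'
#' @param n_samples Number of samples.
#' @param n_informative,n_redundant,n_noise Feature counts by role.
#' @param effect_size Class-conditional mean shift in sd units (default 1).
#' @param positive_fraction Positive class fraction (default 0.10, the
#'   interface-residue imbalance of the curated structure set).
#' @param redundancy_noise_sd Jitter sd added to redundant copies
#'   (default 0.1).
#' @param seed Integer seed; identical configs and seeds give bit-identical
#'   output.
#' @param feature_names Optional column names (e.g.
#'   [residue_feature_names()] for the 40-column catalog layout).
#' @return List: `X` (matrix), `y` (integer 0/1), `roles` (data.frame with
#'   `name`, `role` in informative/redundant/noise, `parent` index of the
#'   informative parent for redundant features).
#' @examples
#' sim <- simulate_feature_dataset(200, n_informative = 2, n_noise = 3,
#'                                 seed = 42)
#' table(sim$y)
#' @export
simulate_feature_dataset <- function(n_samples, n_informative = 3L,
                                     n_redundant = 0L, n_noise = 7L,
                                     effect_size = 1.0,
                                     positive_fraction = 0.10,
                                     redundancy_noise_sd = 0.1,
                                     seed = 1L, feature_names = NULL) {
  p <- n_informative + n_redundant + n_noise
  if (any(c(n_informative, n_redundant, n_noise) < 0) || p < 1L) {
    stop("feature counts must be >= 0 and sum to >= 1")
  }
  if (n_redundant > 0L && n_informative == 0L) {
    stop("redundant features need at least one informative parent")
  }
  if (positive_fraction <= 0 || positive_fraction >= 1) {
    stop("positive_fraction must lie in (0, 1)")
  }
  n_pos <- round(n_samples * positive_fraction)
  if (n_pos < 1L || n_pos >= n_samples) {
    stop("positive_fraction yields a degenerate class split at n = ",
         n_samples)
  }
  parent <- if (n_redundant > 0L) {
    rep_len(seq_len(n_informative), n_redundant)
  } else {
    integer(0)
  }
  withr::with_seed(seed, {
    y <- sample(c(rep(1L, n_pos), rep(0L, n_samples - n_pos)))
    Xi <- matrix(stats::rnorm(n_samples * n_informative), n_samples) +
      effect_size * y
    Xr <- if (n_redundant > 0L) {
      Xi[, parent, drop = FALSE] +
        matrix(stats::rnorm(n_samples * n_redundant,
                            sd = redundancy_noise_sd), n_samples)
    } else {
      matrix(0, n_samples, 0)
    }
    Xn <- matrix(stats::rnorm(n_samples * n_noise), n_samples)
  })
  X <- cbind(Xi, Xr, Xn)
  nm <- if (!is.null(feature_names)) {
    if (length(feature_names) != p) {
      stop("feature_names must have length ", p)
    }
    feature_names
  } else {
    c(sprintf("inf%02d", seq_len(n_informative)),
      sprintf("red%02d", seq_len(n_redundant))[seq_len(n_redundant)],
      sprintf("noise%02d", seq_len(n_noise))[seq_len(n_noise)])
  }
  colnames(X) <- nm
  roles <- data.frame(
    name = nm,
    role = rep(c("informative", "redundant", "noise"),
               c(n_informative, n_redundant, n_noise)),
    parent = c(rep(NA_integer_, n_informative), parent,
               rep(NA_integer_, n_noise)),
    stringsAsFactors = FALSE
  )
  list(X = X, y = y, roles = roles)
}

#' @keywords internal
backbone_template <- function() {
  # heavy-atom offsets (Angstrom) relative to the C-alpha position
  data.frame(
    elety = c("N", "CA", "C", "O", "CB"),
    element = c("N", "C", "C", "O", "C"),
    dx = c(-1.20, 0.00, 1.20, 1.30, 0.00),
    dy = c(0.80, 0.00, 0.80, 2.00, -0.80),
    dz = c(0.00, 0.00, 0.00, 0.00, 1.20),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
chain_ca_coords <- function(n_residues, geometry) {
  i <- seq_len(n_residues)
  if (geometry == "linear") {
    cbind(3.8 * (i - 1L), 0, 0)
  } else {  # ideal alpha-helix: radius 2.3 A, rise 1.5 A, 100 deg/residue
    theta <- (i - 1L) * 100 * pi / 180
    cbind(1.5 * (i - 1L), 2.3 * cos(theta), 2.3 * sin(theta))
  }
}

#' @keywords internal
build_chain_atoms <- function(chain_id, n_residues, geometry, seed,
                              resno_start = 1L) {
  tmpl <- backbone_template()
  ca <- chain_ca_coords(n_residues, geometry)
  aa_pool <- AA1
  aa <- withr::with_seed(seed, sample(aa_pool, n_residues, replace = TRUE))
  atoms <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
    data.frame(
      chain = chain_id, resno = resno_start + i - 1L, icode = "",
      aa = aa[i], elety = tmpl$elety, element = tmpl$element,
      x = ca[i, 1] + tmpl$dx, y = ca[i, 2] + tmpl$dy, z = ca[i, 3] + tmpl$dz,
      stringsAsFactors = FALSE
    )
  }))
  atoms$radius <- unname(VDW_RADII[atoms$element])
  atoms
}

#' Simulate a two-chain structure with a planted contact region
#'
#' Builds a toy dimer: two chains of `n_residues` residues each (linear or
#' ideal-helix backbone with N/CA/C/O/CB heavy atoms), chain B running
#' parallel to chain A at lateral distance `chain_distance` and shifted
#' half a chain along the axis, so a contiguous run of residues on each
#' chain faces the partner and loses accessible area on complexation while
#' the remainder does not. With `chain_distance` large (e.g. 100) the
#' chains do not touch at all.
#'
#' @param n_residues Residues per chain (>= 2).
#' @param n_chains Must be 2 (a dimer); any other value is an error.
#' @param geometry `"linear"` (default) or `"helix"` backbone.
#' @param chain_distance Lateral distance between the chain axes in
#'   Angstrom (default 5, within heavy-atom contact range).
#' @param interface_contact_distance Ground-truth contact cut-off: a
#'   residue is a planted contact when its representative atom lies within
#'   this distance of the partner chain's (default 6 Angstrom).
#' @param seed Integer seed (residue identities).
#' @return List: `structure` (a `ppi_structure`), `contacts` (logical
#'   vector over the residues of the structure, `TRUE` for planted contact
#'   residues), `config`.
#' @examples
#' d <- simulate_dimer(n_residues = 8, seed = 1)
#' sum(d$contacts)
#' @export
simulate_dimer <- function(n_residues = 14L, n_chains = 2L,
                           geometry = c("linear", "helix"),
                           chain_distance = 5.0,
                           interface_contact_distance = 6.0, seed = 1L) {
  geometry <- match.arg(geometry)
  if (n_chains != 2L) {
    stop("simulate_dimer builds dimers only (n_chains must be 2)")
  }
  if (n_residues < 2L) stop("n_residues must be >= 2")
  a <- build_chain_atoms("A", n_residues, geometry, seed)
  b <- build_chain_atoms("B", n_residues, geometry, seed + 1L)
  # partner chain: shifted half a chain along x, chain_distance along -y
  x_shift <- 3.8 * floor(n_residues / 2)
  b$x <- b$x + x_shift
  b$y <- -b$y - chain_distance   # mirror so side chains face chain A
  atoms <- rbind(a, b)
  res_key <- paste(atoms$chain, atoms$resno, sep = "\r")
  atoms$res_index <- match(res_key, unique(res_key))
  struct <- new_ppi_structure(atoms)

  res <- struct$residues
  rc <- cbind(res$rep_x, res$rep_y, res$rep_z)
  in_a <- res$chain == "A"
  dmat <- as.matrix(stats::dist(rc))
  cross <- dmat[in_a, !in_a, drop = FALSE]
  contacts <- logical(nrow(res))
  contacts[in_a] <- apply(cross, 1, min) <= interface_contact_distance
  contacts[!in_a] <- apply(cross, 2, min) <= interface_contact_distance
  list(structure = struct, contacts = contacts,
       config = list(n_residues = n_residues, geometry = geometry,
                     chain_distance = chain_distance,
                     interface_contact_distance = interface_contact_distance,
                     seed = seed))
}
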