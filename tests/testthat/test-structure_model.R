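# Structure parsing, Shrake-Rupley accessibility, and the surface /
# interface labeling rules.

test_that("PDB round-trips preserve residues, chains and file order", {
  s <- toy_structure(cbind(c(0, 4, 8, 12, 16), 0, 0))
  expect_s3_class(s, "ppi_structure")
  expect_equal(length(unique(s$residues$chain)), 1L)
  expect_equal(nrow(s$residues), 5L)

  two <- read_pdb_structure(
    toy_pdb_file(cbind(c(0, 4, 8, 12), 0, 0),
                 chain = c("A", "A", "B", "B")))
  expect_equal(unique(two$residues$chain), c("A", "B"))

  d <- simulate_dimer(n_residues = 6, seed = 3)
  f <- tempfile(fileext = ".pdb")
  write_pdb_structure(d$structure, f)
  back <- read_pdb_structure(f)
  expect_equal(back$residues$aa, d$structure$residues$aa)
  expect_equal(back$atoms$x, d$structure$atoms$x, tolerance = 1e-3)
})

test_that("HETATM-only files are rejected as empty structures", {
  expect_error(read_pdb_structure(hetatm_only_pdb()), "empty structure")
  expect_error(read_pdb_structure(tempfile()), "cannot read")
})

test_that("alternate locations resolve to the highest-occupancy atom", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       9.000   0.000   0.000  0.60  0.00           C",
    "END"), path)
  s <- read_pdb_structure(path)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$x, 9.0)
})

test_that("isolated and well-separated atoms reach the analytic sphere area", {
  one <- toy_structure(c(0, 0, 0))          # carbon, vdw 1.70
  asa1 <- as.numeric(shrake_rupley(one))
  expect_equal(asa1, 4 * pi * 3.1^2, tolerance = 0.01)

  two <- toy_structure(cbind(c(0, 100), 0, 0))
  expect_equal(sum(shrake_rupley(two)), 2 * asa1, tolerance = 1e-9)
})

test_that("contacting atoms agree with a dense-point oracle within 2%", {
  # two carbons at contact distance: occluded lattice at 960 points vs the
  # same algorithm at >= 10^4 point density
  s <- toy_structure(cbind(c(0, 3.4), 0, 0))
  coarse <- attr(shrake_rupley(s, n_points = 960L), "atom_asa")
  dense <- attr(shrake_rupley(s, n_points = 10000L), "atom_asa")
  expect_lt(max(abs(coarse - dense) / dense), 0.02)
  expect_true(all(coarse < 4 * pi * 3.1^2))  # occlusion reduces both
})

test_that("residue ASA sums exactly to atom-level ASA", {
  d <- simulate_dimer(n_residues = 5, seed = 2)
  asa <- shrake_rupley(d$structure, n_points = 240L)
  expect_equal(sum(asa), sum(attr(asa, "atom_asa")))
  expect_true(all(asa >= 0))
})

test_that("adding an atom never increases any existing atom's ASA", {
  base_xyz <- cbind(c(0, 3, 1.5), c(0, 0, 2.5), 0)
  before <- attr(shrake_rupley(toy_structure(base_xyz)), "atom_asa")
  after <- attr(shrake_rupley(toy_structure(rbind(base_xyz, c(1.5, 1, 1)))),
                "atom_asa")
  expect_true(all(after[1:3] <= before + 1e-9))
})

test_that("ASA is invariant under rotation and translation within 1%", {
  xyz <- cbind(c(0, 3, 1.5, 4.5), c(0, 0, 2.5, 2.0), c(0, 1, 0, 1.5))
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  moved <- xyz %*% t(R) + matrix(c(10, -5, 3), nrow(xyz), 3, byrow = TRUE)
  a0 <- as.numeric(shrake_rupley(toy_structure(xyz)))
  a1 <- as.numeric(shrake_rupley(toy_structure(moved)))
  expect_lt(max(abs(a1 - a0) / a0), 0.01)
})

test_that("relative accessibility divides by the per-residue reference", {
  expect_equal(relative_asa(0, "A"), 0)
  expect_equal(relative_asa(274.0, "R"), 1)     # reference value itself
  expect_equal(relative_asa(52, "G"), 0.5)      # manual: 52 / 104
  expect_error(relative_asa(10, "X"), "no max-ASA reference")
  expect_error(relative_asa(10, "Z"), "no max-ASA reference")
})

test_that("surface rule is strictly greater than the 25% threshold", {
  expect_true(label_surface(0.30))
  expect_false(label_surface(0.25))
  expect_false(label_surface(0))
})

test_that("interface rule needs surface status and >= 1 A^2 burial", {
  expect_true(label_interface(50, 49, is_surface = TRUE))
  expect_false(label_interface(50, 49.5, is_surface = TRUE))
  expect_false(label_interface(50, 40, is_surface = FALSE))
})

test_that("label_structure emits the full residue table", {
  d <- simulate_dimer(n_residues = 6, seed = 1)
  lab <- label_structure(d$structure, n_points = 240L)
  expect_named(lab, c("chain", "resnum", "icode", "aa", "asa", "rasa",
                      "masa", "casa", "is_surface", "is_interface"))
  expect_equal(nrow(lab), 12L)
  expect_true(all(lab$is_surface[lab$is_interface]))  # interface => surface
  f <- tempfile(fileext = ".tsv")
  write_labels_tsv(lab, f)
  expect_equal(nrow(read.delim(f)), 12L)
})
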