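# Sample construction: single residue, sliding window, spatial patch.

test_that("sample count always equals the surface-residue count", {
  feats <- toy_feature_matrix(10)
  labels <- rep(c(1L, 0L), 5)
  for (surface in list(rep(c(TRUE, FALSE), 5), rep(TRUE, 10),
                       rep(FALSE, 10))) {
    n_surface <- sum(surface)
    expect_equal(nrow(single_samples(feats, labels, surface)$X), n_surface)
    expect_equal(nrow(window_samples(feats, labels, surface, n = 2)$X),
                 n_surface)
    if (n_surface > 0) {
      expect_equal(nrow(suppressWarnings(
        patch_samples(feats, labels, surface,
                      cbind(seq_len(10), 0, 0), m = 3))$X), n_surface)
    }
  }
})

test_that("single samples carry the 40-dim center vector and its label", {
  feats <- toy_feature_matrix(10)
  surface <- rep(c(TRUE, FALSE), 5)
  s <- single_samples(feats, rep(c(1L, 0L), 5), surface)
  expect_equal(dim(s$X), c(5L, 40L))
  expect_equal(s$X[1, ], feats[1, ])
  expect_equal(s$y, rep(1L, 5))
})

test_that("window samples have dimension (2n+1) x 40 and X-pad the termini", {
  feats <- toy_feature_matrix(20)
  surface <- rep(TRUE, 20)
  labels <- rep(0L, 20)

  w5 <- window_samples(feats, labels, surface, n = 5)
  expect_equal(ncol(w5$X), 11L * 40L)  # window length 11 -> 440 columns
  expect_equal(w5$width, 11L)

  w2 <- window_samples(feats, labels, surface, n = 2)
  # first residue: exactly 2 leading pad positions, then residues 1..3
  expect_equal(unname(w2$X[1, 1:80]), rep(0, 80))
  expect_equal(unname(w2$X[1, 81:120]), unname(feats[1, ]))
  expect_error(window_samples(feats, labels, surface, n = 0), "\\[1, 19\\]")
  expect_error(window_samples(feats, labels, surface, n = 20), "\\[1, 19\\]")
})

test_that("a 1-residue chain with n = 1 is all padding around the center", {
  feats <- toy_feature_matrix(1)
  w <- window_samples(feats, 1L, TRUE, n = 1)
  expect_equal(ncol(w$X), 120L)
  expect_equal(unname(w$X[1, 1:40]), rep(0, 40))
  expect_equal(unname(w$X[1, 41:80]), unname(feats[1, ]))
  expect_equal(unname(w$X[1, 81:120]), rep(0, 40))
})

test_that("reversing the chain reverses the window block order", {
  L <- 9L
  feats <- toy_feature_matrix(L)
  surface <- rep(TRUE, L)
  labels <- rep(0L, L)
  n <- 2L
  fwd <- window_samples(feats, labels, surface, n = n)
  rev_idx <- L:1
  bwd <- window_samples(feats[rev_idx, ], labels[rev_idx],
                        surface[rev_idx], n = n)
  width <- 2L * n + 1L
  D <- 40L
  for (i in c(1L, 5L, 9L)) {
    blocks_f <- matrix(fwd$X[i, ], width, D, byrow = TRUE)
    blocks_b <- matrix(bwd$X[L + 1L - i, ], width, D, byrow = TRUE)
    expect_equal(blocks_b, blocks_f[width:1, ])
  }
})

test_that("patches pick the m-1 nearest residues, center first", {
  feats <- toy_feature_matrix(5)
  coords <- cbind(c(0, 1, 2, 3, 4), 0, 0)
  surface <- c(TRUE, rep(FALSE, 4))
  p <- suppressWarnings(
    patch_samples(feats, rep(0L, 5), surface, coords, m = 3))
  expect_equal(attr(p, "members")[[1]], c(1L, 2L, 3L))
  expect_equal(unname(p$X[1, 1:40]), unname(feats[1, ]))
  expect_equal(unname(p$X[1, 41:80]), unname(feats[2, ]))
})

test_that("m = 1 patches reduce to single samples", {
  feats <- toy_feature_matrix(12)
  coords <- cbind(runif(12), runif(12), runif(12))
  surface <- rep(c(TRUE, FALSE), 6)
  labels <- rep(c(1L, 0L), 6)
  p1 <- patch_samples(feats, labels, surface, coords, m = 1)
  s1 <- single_samples(feats, labels, surface)
  expect_equal(unname(p1$X), unname(s1$X))
  expect_equal(p1$y, s1$y)
})

test_that("patch membership beats every excluded residue (brute force)", {
  set.seed(11)
  L <- 30L
  feats <- toy_feature_matrix(L)
  coords <- matrix(rnorm(L * 3, sd = 8), L, 3)
  surface <- rep(TRUE, L)
  p <- patch_samples(feats, rep(0L, L), surface, coords, m = 10)
  members <- attr(p, "members")
  for (i in seq_len(L)) {
    sel <- members[[i]]
    expect_equal(sel[1], i)                      # center first
    expect_equal(anyDuplicated(sel), 0L)         # unique members
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    excluded <- setdiff(seq_len(L), sel)
    expect_lte(max(d[sel]), min(d[excluded]) + 1e-12)
    # internal order: ascending distance after the center
    expect_true(all(diff(d[sel[-1]]) >= -1e-12))
  }
})

test_that("patches larger than the structure are rejected", {
  feats <- toy_feature_matrix(5)
  expect_error(
    suppressWarnings(patch_samples(feats, rep(0L, 5), rep(TRUE, 5),
                                   cbind(1:5, 0, 0), m = 6)),
    "at least")
  expect_warning(
    patch_samples(feats, rep(0L, 5), rep(TRUE, 5), cbind(1:5, 0, 0), m = 3),
    "outside the usual range")
})

test_that("samples survive a TSV round-trip", {
  feats <- toy_feature_matrix(8)
  w <- window_samples(feats, rep(c(1L, 0L), 4), rep(TRUE, 8), n = 1,
                      centers = data.frame(chain = "A", resno = 1:8))
  f <- tempfile(fileext = ".tsv")
  write_samples_tsv(w, f)
  back <- read_samples_tsv(f)
  expect_equal(unname(back$X), unname(w$X))
  expect_equal(back$y, w$y)
  expect_equal(back$width, w$width)
  expect_equal(back$per_dim, w$per_dim)
  expect_equal(back$mode, "window")
})
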