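# Cross-validated random forests, incremental feature selection, and
# repeated balanced undersampling.

test_that("separable data reaches near-perfect pooled MCC", {
  sim <- simulate_feature_dataset(400, n_informative = 3, n_noise = 2,
                                  effect_size = 6, positive_fraction = 0.5,
                                  seed = 1)
  cv <- cross_validate(sim$X, sim$y, n_trees = 100, k = 5, seed = 1)
  expect_gte(unname(cv$metrics["mcc"]), 0.95)
  expect_equal(sum(cv$counts), 400L)   # pooled folds partition the samples
})

test_that("permuted labels give near-zero MCC", {
  sim <- simulate_feature_dataset(600, n_informative = 3, n_noise = 2,
                                  effect_size = 2, positive_fraction = 0.5,
                                  seed = 2)
  for (s in 0:9) {
    y_perm <- withr::with_seed(s, sample(sim$y))
    cv <- cross_validate(sim$X, y_perm, n_trees = 40, k = 3, seed = s)
    expect_lte(abs(unname(cv$metrics["mcc"])), 0.15)
  }
})

test_that("leave-one-out (k = n) runs on a 10-sample dataset", {
  sim <- simulate_feature_dataset(10, n_informative = 2, n_noise = 1,
                                  effect_size = 3, positive_fraction = 0.5,
                                  seed = 3)
  cv <- cross_validate(sim$X, sim$y, n_trees = 30, k = 10, seed = 3)
  expect_equal(sum(cv$counts), 10L)
})

test_that("identical seeds reproduce identical confusion counts", {
  sim <- simulate_feature_dataset(300, n_informative = 2, n_noise = 3,
                                  effect_size = 1, seed = 4)
  a <- cross_validate(sim$X, sim$y, n_trees = 50, k = 4, seed = 99)
  b <- cross_validate(sim$X, sim$y, n_trees = 50, k = 4, seed = 99)
  expect_identical(unclass(a$counts), unclass(b$counts))
  c2 <- cross_validate(sim$X, sim$y, n_trees = 50, k = 4, seed = 100)
  expect_false(identical(unclass(a$counts), unclass(c2$counts)))
  expect_error(cross_validate(sim$X, rep(1L, 300)), "degenerate")
  expect_error(cross_validate(sim$X, sim$y, k = 1), "fold count")
})

test_that("the IFS curve covers every prefix and certifies its argmax", {
  sim <- simulate_feature_dataset(250, n_informative = 3, n_noise = 3,
                                  effect_size = 2, positive_fraction = 0.4,
                                  seed = 5)
  rk <- mrmr_rank(sim$X, sim$y)
  ifs <- incremental_feature_selection(rk, sim$X, sim$y, n_trees = 40,
                                       k = 3, seed = 5)
  expect_equal(nrow(ifs$curve), 6L)
  expect_equal(ifs$curve$i, 1:6)
  mcc <- ifelse(is.na(ifs$curve$mcc), -Inf, ifs$curve$mcc)
  expect_equal(ifs$optimal_i, which.max(mcc))          # ties -> smallest i
  expect_equal(ifs$optimal_features, rk$feature[seq_len(ifs$optimal_i)])
})

test_that("single-feature data yields a one-point curve with optimum 1", {
  sim <- simulate_feature_dataset(120, n_informative = 1, n_noise = 0,
                                  effect_size = 3, positive_fraction = 0.5,
                                  seed = 6)
  ifs <- incremental_feature_selection(1L, sim$X, sim$y, n_trees = 30,
                                       k = 3, seed = 6)
  expect_equal(nrow(ifs$curve), 1L)
  expect_equal(ifs$optimal_i, 1L)
})

test_that("ranked catalog features expand across window positions", {
  expect_equal(ppisite:::expand_feature_columns(2L, width = 3L, per_dim = 4L),
               c(2L, 6L, 10L))
  # window samples: selecting all catalog features must use every column
  feats <- toy_feature_matrix(30, D = 6L)
  sim_y <- rep(c(1L, 0L), 15)
  w <- window_samples(feats + matrix(rnorm(180), 30, 6),
                      sim_y, rep(TRUE, 30), n = 1)
  ifs <- incremental_feature_selection(1:6, w, n_trees = 20, k = 3, seed = 1)
  expect_equal(nrow(ifs$curve), 6L)
  expect_error(incremental_feature_selection(1:5, w), "permutation")
})

test_that("balanced draws are equal-sized, unique, and vary across repeats", {
  sim <- simulate_feature_dataset(220, n_informative = 2, n_noise = 2,
                                  effect_size = 2, positive_fraction = 0.1,
                                  seed = 7)
  res <- balanced_ensemble_evaluate(sim$X, sim$y, n_trees = 30, k = 3,
                                    repeats = 5, seed = 7)
  n_pos <- sum(sim$y == 1L)
  for (d in res$draws) {
    expect_length(d, n_pos)                       # positives == negatives
    expect_equal(anyDuplicated(d), 0L)            # without replacement
    expect_true(all(sim$y[d] == 0L))
  }
  expect_gt(length(unique(lapply(res$draws, sort))), 1L)
  expect_equal(nrow(res$per_repeat), 5L)
})

test_that("repeats = 1 equals a single balanced evaluation with that seed", {
  sim <- simulate_feature_dataset(220, n_informative = 2, n_noise = 2,
                                  effect_size = 2, positive_fraction = 0.1,
                                  seed = 8)
  res <- balanced_ensemble_evaluate(sim$X, sim$y, n_trees = 30, k = 3,
                                    repeats = 1, seed = 8)
  pos <- which(sim$y == 1L)
  draw <- withr::with_seed(9, sample(which(sim$y == 0L), length(pos)))
  idx <- c(pos, draw)
  cv <- cross_validate(sim$X[idx, ], sim$y[idx], n_trees = 30, k = 3,
                       seed = 9)
  expect_equal(unname(res$metrics),
               unname(as.numeric(cv$metrics)))
  expect_error(balanced_ensemble_evaluate(sim$X, rep(0L, 220)),
               "no positive")
})
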