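test_that("reconstruction error has its documented extremes", {
  W <- matrix(runif(6, 0.1, 1), 3, 2); H <- matrix(runif(8, 0.1, 1), 2, 4)
  A <- W %*% H
  expect_equal(reconstruction_error(A, W, H), 0)
  expect_equal(reconstruction_error(A, W * 0, H), 1)
  expect_error(reconstruction_error(A * 0, W, H), "zero")
})

test_that("similarity matrix computes column cosines", {
  M <- cbind(a = c(1, 1), b = c(2, 2), c = c(1, 0), d = c(0, 3))
  S <- similarity_matrix(M)
  expect_equal(S["a", "b"], 1)
  expect_equal(S["c", "d"], 0)
  expect_equal(S["a", "c"], 1 / sqrt(2))
  expect_true(isSymmetric(unname(S)))
  expect_equal(unname(diag(S)), rep(1, 4))
  Mz <- cbind(M, z = c(0, 0))
  Sz <- similarity_matrix(Mz)
  expect_equal(unname(Sz[, "z"]), rep(0, 5))
  expect_equal(attr(Sz, "zero_columns"), "z")
})

test_that("concordance index is 1 for identical similarity structure and matches the closed form", {
  # identical halves -> identical H -> index exactly 1
  H <- matrix(runif(10, 0.1, 1), 2, 5)
  S <- similarity_matrix(H)
  expect_equal(1 - sqrt(sum((S - S)^2)) / (5 * 4), 1)
  # r = 2, S matrices differing by off-diagonal 1 vs 0 in every split
  S1 <- diag(2); S2 <- matrix(1, 2, 2)
  d <- sqrt(sum((S1 - S2)^2))
  expect_equal(1 - d / (2 * 1), 1 - sqrt(2) / 2)
})

test_that("concordance over sample splits is high in the exact-recovery regime", {
  sim <- simulate_caft_samples(n = 40, noise = 0, seed = 17)
  ci <- concordance_index(sim$A, k = 2, alpha = 0, constraints = toy_cs,
                          n_splits = 4L, n_init = 3L, seed = 5,
                          control = caft_control(max_outer = 120L))
  expect_gte(ci$index, 0.95)
  expect_length(ci$per_split, 4L)
})

test_that("bi-cross-validation recovers exact-rank data and degrades for k too small", {
  sim <- simulate_caft_samples(n = 24, noise = 0, seed = 19)
  bc <- bicrossvalidation(sim$A, k = 2, alpha = 0, row_folds = 3L,
                          col_folds = 5L, n_init = 3L, seed = 7,
                          control = tight_control)
  expect_lt(max(bc$errors), 1e-3)
  # reusing the same folds, a rank-1 model predicts the blocks worse
  bc1 <- bicrossvalidation(sim$A, k = 1, alpha = 0, row_folds = 3L,
                           col_folds = 5L, n_init = 3L, seed = 7,
                           control = tight_control, folds = bc$folds)
  expect_gt(bc1$median, bc$median)
})

test_that("selection grid tabulates all criteria reproducibly", {
  sim <- simulate_caft_samples(n = 20, noise = 0.1, seed = 23)
  ctrl <- caft_control(max_outer = 60L)
  s1 <- select_caft_number(sim$A, constraints = toy_cs, k_values = 1:2,
                           alpha_values = 1e-3, n_splits = 2L,
                           row_folds = 3L, col_folds = 5L, n_init = 2L,
                           seed = 31, control = ctrl)
  s2 <- select_caft_number(sim$A, constraints = toy_cs, k_values = 1:2,
                           alpha_values = 1e-3, n_splits = 2L,
                           row_folds = 3L, col_folds = 5L, n_init = 2L,
                           seed = 31, control = ctrl)
  expect_identical(s1$grid, s2$grid)
  expect_true(all(c("reconstruction_error", "concordance", "bcv_median") %in%
                    names(s1$grid)))
  # planted rank 2: adding the second trait improves reconstruction a lot
  re <- s1$grid$reconstruction_error
  expect_gt(re[1] - re[2], 0.05)
  expect_output(print(s1), "parameter-selection")
})
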