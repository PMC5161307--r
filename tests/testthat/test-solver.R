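test_that("objective value matches its closed form on simple cases", {
  A <- matrix(runif(12, 0.1, 1), 3, 4)
  expect_equal(caft_objective(A, matrix(0, 3, 2), matrix(0, 2, 4), 0),
               sum(A^2))
  W <- matrix(runif(6), 3, 2); H <- matrix(runif(8), 2, 4)
  expect_equal(caft_objective(W %*% H, W, H, 0), 0)
  expect_equal(caft_objective(matrix(1), matrix(1), matrix(1), 0.5), 1)
  expect_error(caft_objective(matrix(NA_real_), matrix(1), matrix(1), 0),
               "NA")
})

test_that("weight update solves the ridge NNLS subproblem", {
  set.seed(3)
  H <- matrix(runif(8, 0.2, 1), 2, 4)
  W0 <- matrix(runif(10), 5, 2)
  res <- update_W(W0 %*% H, H, alpha = 0, control = tight_control)
  expect_equal(res$W, W0, tolerance = 1e-5)
  # ridge limit: huge alpha shrinks W to zero
  res2 <- update_W(W0 %*% H, H, alpha = 1e8, control = tight_control)
  expect_lt(max(res2$W), 1e-6)
})

test_that("trait update handles identity, hard zero, and unconstrained cases", {
  A <- matrix(runif(12, 0.1, 1), 3, 4)
  res <- update_H(A, diag(3), alpha = 0, control = tight_control)
  expect_equal(res$H, A, tolerance = 1e-6)
  # minimize (1-h)^2 s.t. h >= 0 and h <= 0  ->  h = 0
  res2 <- update_H(matrix(1), matrix(1), alpha = 0,
                   F_scaled = matrix(1), control = tight_control)
  expect_equal(res2$H[1, 1], 0, tolerance = 1e-6)
  expect_true(res2$feasible)
})

test_that("both block updates match an independent QP oracle", {
  skip_if_not_installed("pracma")
  set.seed(11)
  for (rep in 1:6) {
    n <- sample(3:8, 1); r <- sample(3:8, 1); k <- sample(1:2, 1)
    alpha <- runif(1, 0.01, 0.5)
    A <- matrix(runif(n * r), n, r)
    H <- matrix(runif(k * r, 0.1, 1), k, r)
    # W update vs per-row bound-constrained QP
    res <- update_W(A, H, alpha, control = tight_control)
    C <- 2 * (H %*% t(H) + diag(alpha, k))
    Wq <- matrix(vapply(seq_len(n), function(i)
      pracma::quadprog(C, -2 * as.numeric(H %*% A[i, ]), lb = rep(0, k))$xmin,
      numeric(k)), n, k, byrow = TRUE)
    fW <- function(W) sum((A - W %*% H)^2) + alpha * sum(W^2)
    expect_lt(abs(fW(res$W) - fW(Wq)) / max(1, fW(Wq)), 1e-5)

    # H update with inequality constraints vs QP on vec(H)
    W <- matrix(runif(n * k, 0.1, 1), n, k)
    Fc <- matrix(0, 2, r)
    Fc[1, 1] <- 1; Fc[1, 2] <- -2
    Fc[2, 2] <- 1; Fc[2, min(3, r)] <- Fc[2, min(3, r)] - 2
    resh <- update_H(A, W, alpha, Fc, control = tight_control)
    expect_lte(resh$max_violation, 1e-6)
    Cb <- kronecker(diag(r), 2 * (crossprod(W) + alpha * matrix(1, k, k)))
    Ain <- matrix(0, 2 * k, k * r)
    for (m in 1:2) for (l in seq_len(k)) for (j in seq_len(r))
      Ain[(m - 1) * k + l, (j - 1) * k + l] <- Fc[m, j]
    qp <- pracma::quadprog(Cb, -2 * as.numeric(crossprod(W, A)),
                           A = Ain, b = rep(0, 2 * k), lb = rep(0, k * r))
    Hq <- matrix(qp$xmin, k, r)
    fH <- function(H) sum((A - W %*% H)^2) + alpha * sum(colSums(H)^2)
    expect_lt(abs(fH(resh$H) - fH(Hq)) / max(1, fH(Hq)), 1e-5)
  }
})

test_that("the fit is deterministic given a seed and validates k", {
  sim <- simulate_caft_samples(n = 12, noise = 0.1, seed = 5)
  ctrl <- caft_control(max_outer = 40L)
  f1 <- caft_nmf(sim$A, 2, alpha = 1e-3, constraints = toy_cs, n_init = 2,
                 seed = 9, control = ctrl)
  f2 <- caft_nmf(sim$A, 2, alpha = 1e-3, constraints = toy_cs, n_init = 2,
                 seed = 9, control = ctrl)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H_scaled, f2$H_scaled)
  expect_error(caft_nmf(sim$A, 6, seed = 1), "k must satisfy")
})

test_that("objective is monotone across outer iterations and the fit is feasible", {
  sim <- simulate_caft_samples(n = 30, noise = 0.2, seed = 21)
  fit <- caft_nmf(sim$A, 2, alpha = 1e-3, constraints = toy_cs, n_init = 2,
                  seed = 4)
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-6 * pmax(1, tr[-length(tr)])))
  expect_true(all(fit$H_scaled >= 0))
  expect_true(all(fit$H >= 0))
  expect_lte(fit$feasibility$max_violation, fit$feasibility$tol)
  # reported objective re-evaluates on the returned factors
  sc <- scale_columns(sim$A)
  expect_equal(fit$objective,
               caft_objective(sc$values, fit$W, fit$H_scaled, fit$alpha),
               tolerance = 1e-8)
})

test_that("noise-free exact-rank data is reconstructed nearly exactly", {
  sim <- simulate_caft_samples(n = 25, noise = 0, seed = 13)
  fit <- caft_nmf(sim$A, 2, alpha = 0, n_init = 3, seed = 2,
                  control = tight_control)
  expect_lt(fit$reconstruction_error, 1e-3)
})

test_that("constrained and unconstrained solutions agree with the scale identity", {
  sim <- simulate_caft_samples(n = 20, noise = 0.1, seed = 31)
  fit <- caft_nmf(sim$A, 2, alpha = 1e-3, constraints = toy_cs, n_init = 2,
                  seed = 6)
  # imposing F on the unscaled H is equivalent to the scaled fit's feasibility
  ck <- check_feasibility(fit$H, toy_cs, tol = 1e-4)
  expect_true(ck$feasible)
})

test_that("fit methods expose factors, residuals, prediction and simulation", {
  sim <- simulate_caft_samples(n = 15, noise = 0.1, seed = 8)
  fit <- caft_nmf(sim$A, 2, alpha = 1e-3, constraints = toy_cs, n_init = 2,
                  seed = 3, control = caft_control(max_outer = 60L))
  expect_equal(dim(coef(fit)), c(2L, 5L))
  expect_equal(coef(fit, "weights"), fit$W)
  expect_equal(fitted(fit) + residuals(fit), fit$A, tolerance = 1e-12)
  Wnew <- predict(fit, sim$A[1:4, ])
  expect_equal(dim(Wnew), c(4L, 2L))
  expect_true(all(Wnew >= 0))
  # in-sample projection reproduces the fitted weights closely
  Win <- predict(fit, sim$A)
  expect_lt(max(abs(Win - fit$W)), 0.05 * max(fit$W))
  sims <- simulate(fit, nsim = 2, seed = 1, noise = 0.1)
  expect_length(sims, 2L)
  expect_true(all(sims[[1]] >= 0))
  expect_output(print(fit), "Constrained NMF fit")
  expect_output(print(summary(fit)), "Dominant markers")
})
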