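#' Control parameters for the constrained NMF solver
#'
#' @param max_outer maximum block-coordinate (outer) iterations.
#' @param tol_outer stop when the relative change of the penalized objective
#'   between outer iterations falls below this value.
#' @param inner_max,inner_tol iteration cap and relative objective tolerance
#'   of the Nesterov-accelerated projected-gradient subproblem solver.
#' @param al_penalty fixed augmented-Lagrangian penalty (also the Uzawa
#'   multiplier step).
#' @param uzawa_max maximum Uzawa (dual ascent) iterations per trait update.
#' @param al_tol feasibility tolerance on the scaled constraints
#'   `max(F_scaled %*% t(H_scaled))`.
#' @return list of class `"caft_control"`.
#' @export
caft_control <- function(max_outer = 200L, tol_outer = 1e-6,
                         inner_max = 250L, inner_tol = 1e-9,
                         al_penalty = 10, uzawa_max = 50L, al_tol = 1e-6) {
  stopifnot(max_outer >= 1, tol_outer > 0, inner_max >= 1, inner_tol > 0,
            al_penalty > 0, uzawa_max >= 1, al_tol > 0)
  structure(list(max_outer = as.integer(max_outer), tol_outer = tol_outer,
                 inner_max = as.integer(inner_max), inner_tol = inner_tol,
                 al_penalty = al_penalty, uzawa_max = as.integer(uzawa_max),
                 al_tol = al_tol),
            class = "caft_control")
}

#' Regularized factorization objective
#'
#' Value of the minimized criterion:
#' `||A - W %*% H||_F^2 + alpha * (||W||_F^2 + sum(colSums(H)^2))`.
#' The regularizer is the squared l2 norm of the columnwise l1 norms of `H`,
#' which promotes markers concentrating in few traits.
#'
#' @param A (scaled) abundance matrix, n x r.
#' @param W weight matrix, n x k.
#' @param H (scaled) trait matrix, k x r.
#' @param alpha regularization strength (>= 0).
#' @return non-negative scalar.
#' @export
caft_objective <- function(A, W, H, alpha) {
  if (anyNA(A) || anyNA(W) || anyNA(H) ||
      any(!is.finite(A)) || any(!is.finite(W)) || any(!is.finite(H)))
    stop("NA or non-finite entries in objective inputs")
  sum((A - W %*% H)^2) + alpha * (sum(W^2) + sum(colSums(H)^2))
}

# Nesterov-accelerated projected gradient descent on the non-negative
# orthant for a convex L-smooth objective; function-value restart keeps the
# iterate sequence monotone.
.fista_nn <- function(X0, grad_fn, obj_fn, L, max_iter, tol) {
  X <- pmax(X0, 0)
  Y <- X
  tk <- 1
  fX <- obj_fn(X)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Xn <- pmax(Y - grad_fn(Y) / L, 0)
    fn <- obj_fn(Xn)
    if (fn > fX) {                      # restart momentum from current iterate
      Y <- X
      tk <- 1
      Xn <- pmax(Y - grad_fn(Y) / L, 0)
      fn <- obj_fn(Xn)
    }
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Y <- Xn + ((tk - 1) / tn) * (Xn - X)
    if (abs(fX - fn) <= tol * max(1, abs(fX))) {
      X <- Xn; fX <- fn
      converged <- TRUE
      break
    }
    X <- Xn; fX <- fn; tk <- tn
  }
  list(X = X, value = fX, iterations = it, converged = converged)
}

.eigmax_sym <- function(M) {
  if (nrow(M) == 0L) return(0)
  max(eigen(M, symmetric = TRUE, only.values = TRUE)$values, 0)
}

#' Ridge-regularized non-negative weight update
#'
#' Solves `min_{W >= 0} ||A - W %*% H||_F^2 + alpha ||W||_F^2` for fixed `H`
#' by Nesterov-accelerated projected gradient with step `1/L`,
#' `L = 2 * lambda_max(H %*% t(H) + alpha I)`. The subproblem is strongly
#' convex for `alpha > 0` (or full-row-rank `H`), with a unique minimizer.
#'
#' @param A (scaled) abundance matrix, n x r.
#' @param H fixed trait matrix, k x r.
#' @param alpha ridge strength.
#' @param W0 optional warm start (defaults to zeros).
#' @param control a [caft_control()] list.
#' @return list with `W`, `value` (subproblem objective), `iterations`,
#'   `converged`.
#' @export
update_W <- function(A, H, alpha, W0 = NULL, control = caft_control()) {
  n <- nrow(A); k <- nrow(H)
  HHt <- H %*% t(H) + diag(alpha, k)
  AHt <- A %*% t(H)
  cA <- sum(A^2)
  if (is.null(W0)) W0 <- matrix(0, n, k)
  L <- 2 * .eigmax_sym(HHt)
  if (L <= 0) return(list(W = W0 * 0, value = cA, iterations = 0L, converged = TRUE))
  obj <- function(W) sum((W %*% HHt) * W) - 2 * sum(W * AHt) + cA
  grad <- function(W) 2 * (W %*% HHt - AHt)
  res <- .fista_nn(W0, grad, obj, L, control$inner_max, control$inner_tol)
  list(W = res$X, value = res$value, iterations = res$iterations,
       converged = res$converged)
}

#' Constrained trait update (augmented Lagrangian / Uzawa)
#'
#' Solves `min_{H >= 0, F %*% t(H) <= 0} ||A - W %*% H||_F^2 +
#' alpha * sum(colSums(H)^2)` for fixed `W`. The inequality constraints are
#' handled by an augmented Lagrangian with multipliers started at zero and a
#' fixed penalty; each primal subproblem is solved by Nesterov-accelerated
#' projected gradient (non-negativity handled by projection) and the
#' multipliers are updated by Uzawa dual ascent with step equal to the
#' penalty, until the largest constraint violation drops below `al_tol`.
#'
#' @param A (scaled) abundance matrix, n x r.
#' @param W fixed weight matrix, n x k.
#' @param alpha regularization strength.
#' @param F_scaled constraint matrix on the scaled trait space (may have zero
#'   rows, in which case a single unconstrained solve is performed).
#' @param H0 optional warm start.
#' @param lambda0 optional warm-started multiplier matrix
#'   (constraints x traits).
#' @param control a [caft_control()] list.
#' @return list with `H`, `lambda`, `max_violation`, `feasible`,
#'   `iterations` (total inner iterations), `uzawa_iterations`, `converged`.
#' @export
update_H <- function(A, W, alpha, F_scaled = NULL, H0 = NULL, lambda0 = NULL,
                     control = caft_control()) {
  k <- ncol(W); r <- ncol(A)
  WtW <- crossprod(W)
  WtA <- crossprod(W, A)
  cA <- sum(A^2)
  if (is.null(H0)) H0 <- matrix(0, k, r)
  f_obj <- function(H) sum((WtW %*% H) * H) - 2 * sum(H * WtA) + cA +
    alpha * sum(colSums(H)^2)
  f_grad <- function(H) {
    G <- 2 * (WtW %*% H - WtA)
    if (alpha > 0) G <- G + 2 * alpha * matrix(colSums(H), k, r, byrow = TRUE)
    G
  }
  L0 <- 2 * (.eigmax_sym(WtW) + alpha * k)
  no_con <- is.null(F_scaled) || nrow(F_scaled) == 0L
  if (no_con) {
    if (L0 <= 0)
      return(list(H = H0 * 0, lambda = NULL, max_violation = -Inf,
                  feasible = TRUE, iterations = 0L, uzawa_iterations = 0L,
                  converged = TRUE))
    res <- .fista_nn(H0, f_grad, f_obj, L0, control$inner_max, control$inner_tol)
    return(list(H = res$X, lambda = NULL, max_violation = -Inf, feasible = TRUE,
                iterations = res$iterations, uzawa_iterations = 0L,
                converged = res$converged))
  }
  Fs <- as.matrix(F_scaled)
  rho <- control$al_penalty
  lambda <- if (is.null(lambda0)) matrix(0, nrow(Fs), k) else lambda0
  L <- L0 + rho * .eigmax_sym(crossprod(Fs))
  al_obj <- function(H) {
    G <- Fs %*% t(H)
    f_obj(H) + sum(pmax(lambda + rho * G, 0)^2 - lambda^2) / (2 * rho)
  }
  al_grad <- function(H) {
    mu <- pmax(lambda + rho * (Fs %*% t(H)), 0)
    f_grad(H) + t(mu) %*% Fs
  }
  H <- H0
  total_inner <- 0L
  uz <- 0L
  mv <- Inf
  while (uz < control$uzawa_max) {
    uz <- uz + 1L
    res <- .fista_nn(H, al_grad, al_obj, L, control$inner_max, control$inner_tol)
    H <- res$X
    total_inner <- total_inner + res$iterations
    G <- Fs %*% t(H)
    mv <- max(G)
    lambda_new <- pmax(lambda + rho * G, 0)
    dual_change <- max(abs(lambda_new - lambda))
    lambda <- lambda_new
    if (mv <= control$al_tol && dual_change <= control$al_tol * rho) break
  }
  list(H = H, lambda = lambda, max_violation = mv,
       feasible = mv <= control$al_tol, iterations = total_inner,
       uzawa_iterations = uz, converged = mv <= control$al_tol)
}

#' Fit combined aggregated functional traits by constrained NMF
#'
#' Factorizes a non-negative samples-by-markers abundance matrix `A` as
#' `A ~ W %*% H` with `k` trait rows in `H`, under non-negativity, optional
#' linear inequality constraints `F_delta %*% t(H) <= 0` on the trait matrix,
#' and a regularizer `alpha * (||W||_F^2 + sum(colSums(H_scaled)^2))`
#' promoting marker sparsity across traits. Columns of `A` are l2-normalized
#' before fitting and the fitted traits are returned on both scales.
#'
#' The non-convex problem is attacked by `n_init` random multi-starts: each
#' start draws `W`, `H` entrywise uniform on (0, 1), rescales the pair so
#' that `||W H||_F = ||A_scaled||_F`, and alternates the constrained trait
#' update ([update_H()]) and the ridge weight update ([update_W()]) until the
#' relative objective change drops below `control$tol_outer`. The start with
#' the smallest reconstruction error `||A_scaled - W H_scaled||_F^2` is
#' returned.
#'
#' @param A non-negative samples-by-markers matrix.
#' @param k number of traits (CAFTs), `1 <= k <= min(n, r)`.
#' @param alpha regularization strength (>= 0).
#' @param constraints a `"caft_constraints"` object (or bare matrix) on the
#'   unscaled marker space, or `NULL` for unconstrained NMF.
#' @param n_init number of random starts.
#' @param seed optional integer seed making the fit reproducible.
#' @param scale if `FALSE`, `A` is assumed already column-scaled and
#'   `constraints` already on the scaled space (used internally by the
#'   model-selection routines).
#' @param zero_policy passed to [scale_columns()].
#' @param control a [caft_control()] list.
#' @return an object of class `"caft_nmf"` with elements `W`, `H`,
#'   `H_scaled`, `D`, `A`, `k`, `alpha`, `objective`, `reconstruction_error`
#'   (relative, on the original scale), `objective_trace`, `inits`
#'   (per-start diagnostics), `feasibility`, `converged`, `seed`, `dropped`.
#' @export
caft_nmf <- function(A, k, alpha = 0, constraints = NULL, n_init = 5L,
                     seed = NULL, scale = TRUE, zero_policy = "drop",
                     control = caft_control()) {
  cl <- match.call()
  A_raw <- abundance_matrix(A)
  if (scale) {
    sc <- scale_columns(A_raw, zero_policy = zero_policy)
    At <- sc$values; D <- sc$D; dropped <- sc$dropped
    A_raw <- A_raw[, colnames(At), drop = FALSE]
  } else {
    At <- A_raw
    D <- stats::setNames(rep(1, ncol(At)), colnames(At))
    dropped <- character(0)
  }
  n <- nrow(At); r <- ncol(At)
  if (k < 1 || k > min(n, r))
    stop("k must satisfy 1 <= k <= min(n, r) = ", min(n, r))

  Fs <- NULL
  if (!is.null(constraints)) {
    FD <- if (inherits(constraints, "caft_constraints")) constraints$F_delta
          else as.matrix(constraints)
    if (!is.null(colnames(FD))) {
      lost <- setdiff(colnames(FD), colnames(At))
      if (length(lost) && any(FD[, lost, drop = FALSE] != 0))
        warning("constraint coefficients on dropped marker(s) ignored: ",
                paste(lost, collapse = ", "))
      FD <- FD[, colnames(At), drop = FALSE]
    } else if (ncol(FD) != r) {
      stop("constraint matrix has ", ncol(FD), " columns; expected ", r)
    }
    Fs <- if (scale) scale_constraints(FD, D) else FD
    if (nrow(Fs) == 0L) Fs <- NULL
  }

  if (!is.null(seed)) set.seed(as.integer(seed))
  normA <- sqrt(sum(At^2))
  best <- NULL
  inits <- vector("list", n_init)
  for (init in seq_len(n_init)) {
    W0 <- matrix(stats::runif(n * k), n, k)
    H0 <- matrix(stats::runif(k * r), k, r)
    s <- normA / sqrt(sum((W0 %*% H0)^2))
    W <- W0 * s; H <- H0 * s
    lambda <- NULL
    trace <- numeric(0)
    f_prev <- Inf
    converged <- FALSE
    feasible <- TRUE
    for (it in seq_len(control$max_outer)) {
      hres <- update_H(At, W, alpha, Fs, H0 = H, lambda0 = lambda,
                       control = control)
      H <- hres$H; lambda <- hres$lambda
      wres <- update_W(At, H, alpha, W0 = W, control = control)
      W <- wres$W
      f <- caft_objective(At, W, H, alpha)
      trace <- c(trace, f)
      if (is.finite(f_prev) &&
          abs(f_prev - f) <= control$tol_outer * max(1, f_prev)) {
        converged <- TRUE
        f_prev <- f
        break
      }
      f_prev <- f
    }
    feasible <- is.null(Fs) || max(Fs %*% t(H)) <= control$al_tol
    recon <- sum((At - W %*% H)^2)
    inits[[init]] <- list(W = W, H = H, objective = f_prev,
                          reconstruction = recon, trace = trace,
                          converged = converged, feasible = feasible,
                          max_violation = if (is.null(Fs)) -Inf else max(Fs %*% t(H)))
    if (feasible && (is.null(best) || recon < inits[[best]]$reconstruction))
      best <- init
  }
  if (is.null(best))
    stop("no initialization reached feasibility within al_tol; ",
         "increase uzawa_max or al_penalty")
  b <- inits[[best]]
  H <- unscale_traits(b$H, D)
  rownames(H) <- rownames(b$H) <- paste0("CAFT_", seq_len(k))
  W <- b$W
  dimnames(W) <- list(rownames(At), rownames(H))
  colnames(H) <- colnames(b$H) <- colnames(At)
  fit <- structure(list(
    W = W, H = H, H_scaled = b$H, D = D, A = A_raw,
    k = k, alpha = alpha,
    objective = b$objective,
    reconstruction_error = sqrt(sum((A_raw - W %*% H)^2)) / sqrt(sum(A_raw^2)),
    objective_trace = b$trace,
    inits = data.frame(
      init = seq_len(n_init),
      objective = vapply(inits, `[[`, 0, "objective"),
      reconstruction = vapply(inits, `[[`, 0, "reconstruction"),
      converged = vapply(inits, `[[`, TRUE, "converged"),
      feasible = vapply(inits, `[[`, TRUE, "feasible"),
      max_violation = vapply(inits, `[[`, 0, "max_violation")),
    best_init = best,
    constraints = if (is.null(constraints)) NULL else constraints,
    F_scaled = Fs,
    feasibility = list(feasible = b$feasible, max_violation = b$max_violation,
                       tol = control$al_tol),
    converged = b$converged,
    control = control, seed = seed, dropped = dropped, call = cl),
    class = "caft_nmf")
  fit
}
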