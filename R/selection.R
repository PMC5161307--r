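#' Relative reconstruction error
#'
#' `||A - W %*% H||_F / ||A||_F`: the proportion of information in `A` not
#' captured by the factorization.
#'
#' @param A abundance matrix.
#' @param W,H factor matrices.
#' @return scalar in `[0, Inf)`; 0 iff the factorization is exact.
#' @export
reconstruction_error <- function(A, W, H) {
  nA <- sqrt(sum(A^2))
  if (nA == 0) stop("A is identically zero")
  sqrt(sum((A - W %*% H)^2)) / nA
}

#' Column-cosine similarity matrix
#'
#' The (j, j') entry is the cosine of the angle between columns j and j' of
#' `M`. Cosines involving an all-zero column are set to 0 and the affected
#' columns are recorded in the `"zero_columns"` attribute.
#'
#' @param M numeric matrix.
#' @return symmetric matrix with unit diagonal (for nonzero columns).
#' @export
similarity_matrix <- function(M) {
  M <- as.matrix(M)
  nrm <- sqrt(colSums(M^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  Mn <- sweep(M, 2L, nrm, "/")
  S <- crossprod(Mn)
  S[zero, ] <- 0
  S[, zero] <- 0
  attr(S, "zero_columns") <- colnames(M)[zero]
  S
}

#' Concordance of trait matrices across sample splits
#'
#' For each of `n_splits` repetitions, the rows of the column-scaled
#' abundance matrix are split into two halves, the constrained NMF is fitted
#' on each half (full multi-start), and the column-cosine similarity
#' matrices of the two scaled trait matrices are compared. The index is
#' `1 - mean(||S1 - S2||_F) / (r * (r - 1))`; it equals 1 exactly when every
#' split yields identical similarity structure.
#'
#' @param A abundance matrix (raw scale; column scaling is done once on the
#'   full matrix and shared by both halves).
#' @param k,alpha factorization parameters.
#' @param constraints optional `"caft_constraints"` object (unscaled space).
#' @param n_splits number of random half-splits.
#' @param n_init multi-start count per half fit.
#' @param seed seed for the split draws and fits.
#' @param control solver control.
#' @param splits optional list of precomputed row-index vectors (first
#'   halves), overriding the random draws, so the same splits can be reused
#'   across a parameter grid.
#' @return list with `index`, `per_split` (Frobenius distances), `splits`.
#' @export
concordance_index <- function(A, k, alpha = 0, constraints = NULL,
                              n_splits = 40L, n_init = 5L, seed = NULL,
                              control = caft_control(), splits = NULL) {
  sc <- scale_columns(A)
  At <- sc$values
  n <- nrow(At); r <- ncol(At)
  if (n < 2L) stop("need at least two samples to split")
  if (k > floor(n / 2)) stop("k exceeds half-split sample count")
  Fs <- NULL
  if (!is.null(constraints)) {
    FD <- if (inherits(constraints, "caft_constraints")) constraints$F_delta
          else as.matrix(constraints)
    if (!is.null(colnames(FD))) FD <- FD[, colnames(At), drop = FALSE]
    Fs <- scale_constraints(FD, sc$D)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(splits))
    splits <- replicate(n_splits, sample.int(n, floor(n / 2)), simplify = FALSE)
  dists <- vapply(splits, function(idx) {
    f1 <- caft_nmf(At[idx, , drop = FALSE], k, alpha, constraints = Fs,
                   n_init = n_init, scale = FALSE, control = control)
    f2 <- caft_nmf(At[-idx, , drop = FALSE], k, alpha, constraints = Fs,
                   n_init = n_init, scale = FALSE, control = control)
    S1 <- similarity_matrix(f1$H_scaled)
    S2 <- similarity_matrix(f2$H_scaled)
    sqrt(sum((S1 - S2)^2))
  }, 0)
  list(index = 1 - mean(dists) / (r * (r - 1)), per_split = dists,
       splits = splits)
}

#' Bi-cross-validation error of the unconstrained factorization
#'
#' Gabriel-style holdout: rows and columns of `A` are partitioned into
#' folds; for each (row fold I, column fold J) the held-out block
#' `A[I, J]` is predicted from the factorization `(W1, H1)` of the training
#' block `A[-I, -J]` as `A[I, -J] %*% pinv(H1) %*% pinv(W1) %*% A[-I, J]`
#' (Moore-Penrose pseudo-inverses), and the relative Frobenius error of the
#' block is recorded. Column splits break the metabolic adjacency on which
#' the constraints are built, so this criterion is always computed without
#' constraints.
#'
#' @param A abundance matrix.
#' @param k,alpha factorization parameters.
#' @param row_folds,col_folds fold counts (at most `nrow(A)` / `ncol(A)`).
#' @param n_init multi-start count per training fit.
#' @param seed seed for fold assignment and fits.
#' @param control solver control.
#' @param folds optional list with elements `row`, `col` (fold-id vectors)
#'   to reuse one assignment across a parameter grid.
#' @return list with `errors` (row-fold x col-fold matrix), `median`,
#'   `folds`.
#' @export
bicrossvalidation <- function(A, k, alpha = 0, row_folds = 10L, col_folds = 10L,
                              n_init = 5L, seed = NULL,
                              control = caft_control(), folds = NULL) {
  A <- abundance_matrix(A)
  n <- nrow(A); r <- ncol(A)
  stopifnot(row_folds >= 2L, col_folds >= 2L, row_folds <= n, col_folds <= r)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(folds))
    folds <- list(row = sample(rep_len(seq_len(row_folds), n)),
                  col = sample(rep_len(seq_len(col_folds), r)))
  errs <- matrix(NA_real_, row_folds, col_folds)
  for (i in seq_len(row_folds)) {
    I <- folds$row == i
    for (j in seq_len(col_folds)) {
      J <- folds$col == j
      A11 <- A[!I, !J, drop = FALSE]
      if (k > min(dim(A11))) stop("k exceeds training block dimensions")
      fit <- caft_nmf(A11, k, alpha, constraints = NULL, n_init = n_init,
                      control = control)
      pred <- A[I, !J, drop = FALSE] %*% MASS::ginv(fit$H) %*%
        MASS::ginv(fit$W) %*% A[!I, J, drop = FALSE]
      nb <- sqrt(sum(A[I, J]^2))
      errs[i, j] <- if (nb == 0) NA_real_ else
        sqrt(sum((A[I, J] - pred)^2)) / nb
    }
  }
  list(errors = errs, median = stats::median(errs, na.rm = TRUE),
       folds = folds)
}

#' Tabulate the three selection criteria over a parameter grid
#'
#' Computes, for every combination of `k_values` and `alpha_values`, the
#' relative reconstruction error of the constrained fit, the per-split
#' concordance of the trait matrix, and the per-block bi-cross-validation
#' error of the unconstrained fit. Fold and split assignments are drawn once
#' and reused across the whole grid so the criteria are comparable. No
#' automatic choice is made: the report exposes curves and medians, and the
#' working rule is to take the parameter value optimizing concordance while
#' keeping the other two criteria acceptable.
#'
#' @param A abundance matrix.
#' @param constraints optional `"caft_constraints"` object.
#' @param k_values,alpha_values grids to explore.
#' @param n_splits concordance splits.
#' @param row_folds,col_folds bi-cross-validation folds.
#' @param n_init multi-start count per fit.
#' @param seed master seed.
#' @param control solver control.
#' @return an object of class `"caft_selection"`: list with `grid`
#'   (data.frame of medians per parameter pair), `concordance`, `bcv`
#'   (per-pair detail lists), `folds`, `splits`.
#' @export
select_caft_number <- function(A, constraints = NULL, k_values = 2:6,
                               alpha_values = 1e-3, n_splits = 10L,
                               row_folds = 5L, col_folds = 5L, n_init = 5L,
                               seed = NULL, control = caft_control()) {
  stopifnot(length(k_values) >= 1L, length(alpha_values) >= 1L)
  A <- abundance_matrix(A)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(A); r <- ncol(A)
  splits <- replicate(n_splits, sample.int(n, floor(n / 2)), simplify = FALSE)
  folds <- list(row = sample(rep_len(seq_len(row_folds), n)),
                col = sample(rep_len(seq_len(col_folds), r)))
  grid <- expand.grid(k = k_values, alpha = alpha_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$reconstruction_error <- NA_real_
  grid$concordance <- NA_real_
  grid$bcv_median <- NA_real_
  conc <- vector("list", nrow(grid))
  bcv <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    kk <- grid$k[g]; aa <- grid$alpha[g]
    fit <- caft_nmf(A, kk, aa, constraints = constraints, n_init = n_init,
                    seed = if (is.null(seed)) NULL else seed + g,
                    control = control)
    grid$reconstruction_error[g] <- fit$reconstruction_error
    ci <- concordance_index(A, kk, aa, constraints = constraints,
                            n_init = n_init, control = control,
                            seed = if (is.null(seed)) NULL else seed + g,
                            splits = splits)
    conc[[g]] <- ci$per_split
    grid$concordance[g] <- ci$index
    bc <- bicrossvalidation(A, kk, aa, row_folds, col_folds, n_init = n_init,
                            seed = if (is.null(seed)) NULL else seed + g,
                            control = control, folds = folds)
    bcv[[g]] <- bc$errors
    grid$bcv_median[g] <- bc$median
  }
  structure(list(grid = grid, concordance = conc, bcv = bcv,
                 folds = folds, splits = splits, seed = seed),
            class = "caft_selection")
}

#' @export
print.caft_selection <- function(x, ...) {
  cat("CAFT parameter-selection report (",
      nrow(x$grid), " parameter pairs )\n", sep = "")
  print(x$grid, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.caft_selection <- function(x, ...) {
  g <- x$grid
  op <- graphics::par(mfrow = c(1, 3)); on.exit(graphics::par(op))
  for (crit in c("reconstruction_error", "bcv_median", "concordance")) {
    graphics::plot(g$k, g[[crit]], type = "b", xlab = "k", ylab = crit, ...)
  }
  invisible(x)
}
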