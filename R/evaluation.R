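#' Agreement between total marker abundance and total fitted trait abundance
#'
#' Pearson correlation between the row sums of `A` (the per-sample fraction
#' of the metagenome devoted to the modelled markers) and the row sums of
#' the reconstruction `W %*% H`.
#'
#' @param A abundance matrix.
#' @param W,H fitted factors.
#' @return scalar correlation, or `NA` with a warning when either row-sum
#'   vector is constant.
#' @export
rowsum_agreement <- function(A, W, H) {
  ra <- rowSums(A)
  rf <- rowSums(W %*% H)
  if (stats::sd(ra) == 0 || stats::sd(rf) == 0) {
    warning("constant row sums: correlation undefined")
    return(NA_real_)
  }
  stats::cor(ra, rf)
}

#' Preservation of between-sample geometry in the weight space
#'
#' Columns of `A` and `W` are l1-normalized (each column then gives the
#' repartition of one marker / one CAFT across samples), full Euclidean
#' distance matrices between sample rows are computed in both spaces, and
#' for each sample the Pearson correlation between its distances to all
#' other samples in the two spaces is reported. Values near 1 mean the
#' dimension reduction preserves the sample geometry.
#'
#' @param A abundance matrix (n x r), `n >= 3`.
#' @param W weight matrix (n x k).
#' @return list of class `"caft_preservation"`: `correlations` (length-n
#'   vector C_i), `quantiles`, `degenerate` (samples whose distance vectors
#'   are constant).
#' @export
distance_preservation <- function(A, W) {
  A <- as.matrix(A); W <- as.matrix(W)
  n <- nrow(A)
  if (n < 3L) stop("need at least three samples")
  if (nrow(W) != n) stop("A and W must have the same number of rows")
  l1 <- function(M) {
    cs <- colSums(M)
    if (any(cs == 0)) stop("all-zero column(s); cannot l1-normalize")
    sweep(M, 2L, cs, "/")
  }
  dA <- as.matrix(stats::dist(l1(A)))
  dW <- as.matrix(stats::dist(l1(W)))
  C <- vapply(seq_len(n), function(i) {
    a <- dA[i, -i]; w <- dW[i, -i]
    if (stats::sd(a) == 0 || stats::sd(w) == 0) return(NA_real_)
    stats::cor(a, w)
  }, 0)
  names(C) <- rownames(A)
  structure(list(correlations = C,
                 quantiles = stats::quantile(C, c(0, .01, .25, .5, .75, 1),
                                             na.rm = TRUE),
                 degenerate = names(C)[is.na(C)]),
            class = "caft_preservation")
}

#' @export
print.caft_preservation <- function(x, ...) {
  cat("Distance preservation over", length(x$correlations), "samples\n")
  print(signif(x$quantiles, 3))
  if (length(x$degenerate))
    cat("degenerate samples:", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Align estimated traits to a reference by optimal assignment
#'
#' Finds the row permutation of `H_est` maximizing the total cosine
#' similarity with the rows of `H_ref` (exhaustive over permutations, the
#' trait count being small) and reports the matched per-row cosines.
#' Cosine similarity is invariant to positive rescaling of either side.
#'
#' @param H_est,H_ref trait matrices of identical dimensions.
#' @return list with `permutation` (H_est row assigned to each H_ref row),
#'   `similarities` (per matched pair), `mean_similarity`.
#' @export
align_traits <- function(H_est, H_ref) {
  H_est <- as.matrix(H_est); H_ref <- as.matrix(H_ref)
  if (!all(dim(H_est) == dim(H_ref)))
    stop("trait matrices must have identical dimensions")
  k <- nrow(H_ref)
  if (k > 8L) stop("exhaustive alignment supported for k <= 8")
  rn <- function(M) {
    nr <- sqrt(rowSums(M^2))
    if (any(nr == 0)) stop("zero trait row; cosine undefined")
    M / nr
  }
  S <- rn(H_ref) %*% t(rn(H_est))   # k x k cosines: ref rows x est rows
  perms <- .permutations(k)
  tot <- vapply(seq_len(nrow(perms)), function(p)
    sum(S[cbind(seq_len(k), perms[p, ])]), 0)
  best <- unname(perms[which.max(tot), ])
  sims <- unname(S[cbind(seq_len(k), best)])
  list(permutation = best, similarities = sims, mean_similarity = mean(sims))
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}
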