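#' @export
print.caft_nmf <- function(x, ...) {
  cat("Constrained NMF fit:", x$k, "CAFTs,", nrow(x$W), "samples,",
      ncol(x$H), "markers\n")
  cat(sprintf("alpha = %g, objective = %.6g, relative reconstruction error = %.4g\n",
              x$alpha, x$objective, x$reconstruction_error))
  if (!is.null(x$F_scaled))
    cat(sprintf("constraints: %d rows, max violation %.3g (tol %.1g)\n",
                nrow(x$F_scaled), x$feasibility$max_violation,
                x$feasibility$tol))
  else cat("constraints: none\n")
  cat("best of", nrow(x$inits), "starts (init", x$best_init,
      if (x$converged) ", converged )\n" else ", iteration cap reached )\n")
  invisible(x)
}

#' @export
summary.caft_nmf <- function(object, ...) {
  H1 <- l1_normalize_traits(object$H)
  top <- t(apply(H1, 1L, function(h) {
    o <- order(h, decreasing = TRUE)[seq_len(min(5L, length(h)))]
    paste0(colnames(H1)[o], " (", signif(h[o], 2), ")", collapse = ", ")
  }))
  out <- list(fit = object,
              trait_profiles = H1,
              top_markers = drop(top),
              weight_summary = apply(object$W, 2L, stats::quantile,
                                     probs = c(0, .25, .5, .75, 1)),
              inits = object$inits)
  class(out) <- "summary.caft_nmf"
  out
}

#' @export
print.summary.caft_nmf <- function(x, ...) {
  print(x$fit)
  cat("\nDominant markers per CAFT (l1-normalized trait rows):\n")
  for (l in seq_along(x$top_markers))
    cat("  ", rownames(x$trait_profiles)[l], ": ", x$top_markers[l], "\n", sep = "")
  cat("\nWeight distribution per CAFT:\n")
  print(signif(x$weight_summary, 3))
  invisible(x)
}

#' Extract fitted factors
#'
#' @param object a `"caft_nmf"` fit.
#' @param which `"traits"` for the trait matrix H (optionally l1- or
#'   l2-scaled versions), `"weights"` for W.
#' @param scaled return the column-scaled trait matrix used internally.
#' @param ... unused.
#' @export
coef.caft_nmf <- function(object, which = c("traits", "weights"),
                          scaled = FALSE, ...) {
  which <- match.arg(which)
  if (which == "weights") return(object$W)
  if (scaled) object$H_scaled else object$H
}

#' @export
fitted.caft_nmf <- function(object, ...) object$W %*% object$H

#' @export
residuals.caft_nmf <- function(object, ...) object$A - fitted(object)

#' Project new samples onto fitted traits
#'
#' Estimates non-negative weights for new samples with the trait matrix held
#' fixed, by the same ridge-regularized non-negative least-squares update
#' used during fitting (on the fit's column scaling).
#'
#' @param object a `"caft_nmf"` fit.
#' @param newdata samples-by-markers matrix with the fit's marker columns.
#' @param ... unused.
#' @return weight matrix, rows = new samples, columns = CAFTs.
#' @export
predict.caft_nmf <- function(object, newdata, ...) {
  newdata <- abundance_matrix(newdata)
  if (!all(colnames(object$H) %in% colnames(newdata)))
    stop("newdata is missing fitted marker columns")
  At <- sweep(newdata[, colnames(object$H), drop = FALSE], 2L, object$D, "/")
  res <- update_W(At, object$H_scaled, object$alpha, control = object$control)
  W <- res$W
  dimnames(W) <- list(rownames(newdata), rownames(object$H))
  W
}

#' Plot trait compositions
#'
#' Barplot of the l1-normalized trait rows: the relative frequency of each
#' functional marker within each CAFT.
#'
#' @param x a `"caft_nmf"` fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.caft_nmf <- function(x, ...) {
  H1 <- l1_normalize_traits(x$H)
  graphics::barplot(H1, beside = TRUE, legend.text = rownames(H1),
                    las = 2, ylab = "relative marker frequency",
                    main = "CAFT compositions", ...)
  invisible(x)
}

#' Simulate abundance matrices from a fitted model
#'
#' Draws replicates of `W %*% H` perturbed by multiplicative Gaussian noise,
#' `a_ij = (WH)_ij * (1 + noise * eps_ij)`, clipped at zero — the same noise
#' model as the planted-trait generator.
#'
#' @param object a `"caft_nmf"` fit.
#' @param nsim number of replicates.
#' @param seed optional seed.
#' @param noise multiplicative noise level.
#' @param ... unused.
#' @return a list of `nsim` matrices.
#' @export
simulate.caft_nmf <- function(object, nsim = 1, seed = NULL, noise = 0.2, ...) {
  if (!is.null(seed)) set.seed(seed)
  B <- fitted(object)
  replicate(nsim, pmax(B * (1 + noise * stats::rnorm(length(B))), 0),
            simplify = FALSE)
}
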