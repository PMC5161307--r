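#' Validate a samples-by-markers abundance matrix
#'
#' Coerces `x` to a numeric matrix and checks the invariants expected by all
#' downstream functions: non-negative finite entries, at least one sample and
#' one marker, and unique sample/marker identifiers. Row names are sample ids,
#' column names are functional-marker ids (KEGG orthology groups, GH/PL
#' families, or merged-KO labels); defaults are generated when missing.
#'
#' @param x a numeric matrix or data.frame, samples in rows, markers in columns.
#' @param sample_ids,marker_ids optional character vectors overriding dimnames.
#' @return a numeric matrix with complete, unique dimnames.
#' @export
abundance_matrix <- function(x, sample_ids = NULL, marker_ids = NULL) {
  A <- as.matrix(x)
  storage.mode(A) <- "double"
  if (nrow(A) < 1L || ncol(A) < 1L)
    stop("abundance matrix must have at least one sample and one marker")
  if (anyNA(A) || any(!is.finite(A)))
    stop("abundance matrix contains NA or non-finite entries")
  if (any(A < 0))
    stop("abundance matrix contains negative entries")
  if (!is.null(sample_ids)) rownames(A) <- sample_ids
  if (!is.null(marker_ids)) colnames(A) <- marker_ids
  if (is.null(rownames(A))) rownames(A) <- paste0("sample_", seq_len(nrow(A)))
  if (is.null(colnames(A))) colnames(A) <- paste0("marker_", seq_len(ncol(A)))
  if (anyDuplicated(rownames(A))) stop("duplicated sample ids")
  if (anyDuplicated(colnames(A))) stop("duplicated marker ids")
  A
}

#' Column-wise l2 scaling of an abundance matrix
#'
#' Scales each marker column to unit Euclidean norm. The scaling vector `D`
#' (the per-column l2 norms) is retained so that `A = values %*% diag(D)` and
#' fitted trait matrices can be mapped back to the original abundance scale
#' with [unscale_traits()]. Markers absent from every sample have zero norm
#' and cannot be scaled; they are dropped with a warning (`zero_policy =
#' "drop"`, the default) or trigger an error naming the marker
#' (`zero_policy = "error"`).
#'
#' @param A non-negative samples-by-markers matrix (see [abundance_matrix()]).
#' @param zero_policy how to handle all-zero marker columns.
#' @return an object of class `"caft_scaled"`: a list with elements `values`
#'   (the scaled matrix), `D` (named vector of column norms for retained
#'   markers) and `dropped` (character vector of removed marker ids).
#' @export
scale_columns <- function(A, zero_policy = c("drop", "error")) {
  zero_policy <- match.arg(zero_policy)
  A <- abundance_matrix(A)
  D <- sqrt(colSums(A^2))
  zero <- D == 0
  if (any(zero)) {
    bad <- colnames(A)[zero]
    if (zero_policy == "error")
      stop("marker(s) with all-zero abundance: ", paste(bad, collapse = ", "))
    warning("dropping all-zero marker column(s): ", paste(bad, collapse = ", "))
    A <- A[, !zero, drop = FALSE]
    D <- D[!zero]
  } else {
    bad <- character(0)
  }
  values <- sweep(A, 2L, D, "/")
  structure(list(values = values, D = D, dropped = bad),
            class = "caft_scaled")
}

#' @export
print.caft_scaled <- function(x, ...) {
  cat("Column-scaled abundance matrix:",
      nrow(x$values), "samples x", ncol(x$values), "markers\n")
  if (length(x$dropped))
    cat("dropped all-zero markers:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Map a scaled trait matrix back to the abundance scale
#'
#' Given a trait matrix fitted against the column-scaled abundances and the
#' scaling vector `D`, recovers `H = H_scaled %*% diag(D)`.
#'
#' @param H_scaled k-by-r non-negative matrix of scaled trait compositions.
#' @param D scaling vector of length r (per-marker column norms).
#' @return the unscaled trait matrix, same dimnames as `H_scaled`.
#' @export
unscale_traits <- function(H_scaled, D) {
  H_scaled <- as.matrix(H_scaled)
  if (ncol(H_scaled) != length(D))
    stop("length of D (", length(D), ") does not match trait columns (",
         ncol(H_scaled), ")")
  sweep(H_scaled, 2L, D, "*")
}

#' Row-wise l1 normalization of a trait matrix
#'
#' Each trait row is divided by its sum, giving the relative frequencies of
#' functional markers within the subcommunity the trait characterizes.
#'
#' @param H non-negative trait matrix, one CAFT per row.
#' @return matrix with unit row sums.
#' @export
l1_normalize_traits <- function(H) {
  H <- as.matrix(H)
  rs <- rowSums(H)
  if (any(rs <= 0)) {
    bad <- if (is.null(rownames(H))) which(rs <= 0) else rownames(H)[rs <= 0]
    stop("trait row(s) with non-positive sum: ", paste(bad, collapse = ", "))
  }
  sweep(H, 1L, rs, "/")
}

#' Read / write an abundance matrix as TSV
#'
#' TSV dialect: first column holds sample ids, header row holds marker ids.
#'
#' @param file path to a tab-separated file.
#' @rdname abundance_io
#' @return `read_abundance()` returns a validated abundance matrix.
#' @export
read_abundance <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  A <- as.matrix(df[, -1L, drop = FALSE])
  abundance_matrix(A, sample_ids = ids)
}

#' @param A matrix to write.
#' @rdname abundance_io
#' @export
write_abundance <- function(A, file) {
  df <- data.frame(sample_id = rownames(A), A, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
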