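#' Resolve overlapping domain annotations on a gene
#'
#' Protein regions of one gene may match several GH/PL family models. For
#' every pair of hits on the same gene whose intervals overlap: (1) if the
#' overlap length is at most `overlap_frac` of the shorter matched module,
#' both hits stand; (2) otherwise, if one e-value is at least
#' `evalue_factor` times smaller than the other, only the better hit
#' stands; (3) otherwise both hits are treated as erroneous. Decisions are
#' taken on every conflicting pair, and a hit discarded by any pair is
#' removed from the accepted set, so the result does not depend on the input
#' order. Intervals are 1-based inclusive; overlap length is
#' `max(0, min(end) - max(start) + 1)`.
#'
#' @param hits data.frame with columns `gene_id`, `family`, `start`, `end`,
#'   `e_value`.
#' @param overlap_frac tolerated overlap as a fraction of the shorter
#'   module.
#' @param evalue_factor e-value ratio above which the better hit wins.
#' @return the accepted subset of `hits` (same columns).
#' @export
resolve_overlaps <- function(hits, overlap_frac = 0.10, evalue_factor = 100) {
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "family", "start", "end", "e_value") %in%
                  names(hits)))
  if (any(hits$start > hits$end)) stop("malformed interval: start > end")
  if (any(hits$e_value <= 0)) stop("e-values must be positive")
  keep <- rep(TRUE, nrow(hits))
  for (g in unique(hits$gene_id)) {
    idx <- which(hits$gene_id == g)
    if (length(idx) < 2L) next
    for (ii in seq_along(idx)[-length(idx)]) {
      for (jj in seq.int(ii + 1L, length(idx))) {
        i <- idx[ii]; j <- idx[jj]
        ov <- min(hits$end[i], hits$end[j]) -
          max(hits$start[i], hits$start[j]) + 1L
        if (ov <= 0) next
        len_i <- hits$end[i] - hits$start[i] + 1L
        len_j <- hits$end[j] - hits$start[j] + 1L
        if (ov <= overlap_frac * min(len_i, len_j)) next   # rule 1
        ei <- hits$e_value[i]; ej <- hits$e_value[j]
        if (ej / ei >= evalue_factor) {                    # rule 2
          keep[j] <- FALSE
        } else if (ei / ej >= evalue_factor) {
          keep[i] <- FALSE
        } else {                                           # rule 3
          keep[i] <- FALSE; keep[j] <- FALSE
        }
      }
    }
  }
  hits[keep, , drop = FALSE]
}

#' Aggregate gene frequencies into a marker abundance matrix
#'
#' Sums per-gene frequencies into per-marker totals. A gene annotated to
#' several markers contributes its frequency in equal parts to each of them,
#' so mass is conserved. Marker groups whose members proxy parts of the same
#' enzyme are then replaced by a single merged marker whose abundance is the
#' arithmetic mean of the members' totals.
#'
#' @param gene_freqs genes-by-samples non-negative matrix (rownames =
#'   gene ids).
#' @param annotations named list mapping gene id to a non-empty character
#'   vector of marker ids.
#' @param merge_groups optional named list mapping a merged-marker id to the
#'   member marker ids it replaces.
#' @return a samples-by-markers [abundance_matrix()].
#' @export
aggregate_markers <- function(gene_freqs, annotations, merge_groups = NULL) {
  gene_freqs <- as.matrix(gene_freqs)
  if (is.null(rownames(gene_freqs))) stop("gene_freqs needs gene id rownames")
  if (any(lengths(annotations) == 0L)) stop("empty marker list in annotations")
  miss <- setdiff(names(annotations), rownames(gene_freqs))
  if (length(miss))
    stop("annotated gene(s) missing from gene_freqs: ",
         paste(miss, collapse = ", "))
  markers <- sort(unique(unlist(annotations)))
  M <- matrix(0, length(markers), ncol(gene_freqs),
              dimnames = list(markers, colnames(gene_freqs)))
  for (g in names(annotations)) {
    ms <- annotations[[g]]
    M[ms, ] <- M[ms, , drop = FALSE] +
      matrix(gene_freqs[g, ] / length(ms), length(ms), ncol(M), byrow = TRUE)
  }
  if (!is.null(merge_groups)) {
    for (grp in names(merge_groups)) {
      members <- merge_groups[[grp]]
      unknown <- setdiff(members, rownames(M))
      if (length(unknown))
        stop("merge group '", grp, "' references unknown marker(s): ",
             paste(unknown, collapse = ", "))
      merged <- colMeans(M[members, , drop = FALSE])
      M <- M[setdiff(rownames(M), members), , drop = FALSE]
      M <- rbind(M, matrix(merged, 1L, ncol(M),
                           dimnames = list(grp, colnames(M))))
    }
    M <- M[order(rownames(M)), , drop = FALSE]
  }
  abundance_matrix(t(M))
}

#' Read a distilled domain-hit table
#'
#' TSV with columns `gene_id`, `family`, `start`, `end`, `e_value` (a
#' pre-parsed form of a domain-table scan output).
#'
#' @param file path to TSV.
#' @return data.frame suitable for [resolve_overlaps()].
#' @export
read_domain_hits <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}
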