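#' Construct a metabolic reaction graph
#'
#' The graph describes the metabolic process whose gene markers are being
#' factorized: metabolites are nodes, each classified as intracellular
#' (retained within cells, hence eligible for production/consumption balance
#' constraints) or extracellular (exchanged with the environment, never
#' constrained). Each reaction record maps one functional marker to the sets of
#' metabolites its reaction produces and consumes; a marker may appear in
#' several reaction records, and markers with no reaction (e.g. GH/PL
#' hydrolase families, which are not substrate-specific) are carried along
#' with all-zero incidence columns.
#'
#' @param metabolites data.frame with columns `id`, `status`
#'   (`"intracellular"` or `"extracellular"`) and optionally `specific`
#'   (logical; whether the metabolite is specifically involved in the process,
#'   used by the gray-zone classification rule).
#' @param reactions data.frame with columns `marker_id`, `produces`,
#'   `consumes`; the last two are comma-separated metabolite ids (empty string
#'   for none) or list columns of character vectors.
#' @param marker_ids ordered character vector of all markers, including
#'   markers absent from `reactions`; defaults to the markers appearing in
#'   `reactions`.
#' @return an object of class `"metabolic_graph"`.
#' @export
metabolic_graph <- function(metabolites, reactions, marker_ids = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "status") %in% names(metabolites)))
  metabolites$id <- as.character(metabolites$id)
  if (anyDuplicated(metabolites$id)) stop("duplicated metabolite ids")
  if (!all(metabolites$status %in% c("intracellular", "extracellular")))
    stop("metabolite status must be 'intracellular' or 'extracellular'")
  if (is.null(metabolites$specific)) metabolites$specific <- NA

  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stopifnot(all(c("marker_id", "produces", "consumes") %in% names(reactions)))
  split_ids <- function(x) {
    if (is.list(x)) return(lapply(x, as.character))
    lapply(strsplit(as.character(x), ","), function(v) trimws(v[nzchar(trimws(v))]))
  }
  prod <- split_ids(reactions$produces)
  cons <- split_ids(reactions$consumes)
  used <- unique(unlist(c(prod, cons)))
  unknown <- setdiff(used, metabolites$id)
  if (length(unknown))
    stop("reaction references undeclared metabolite(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(marker_ids)) marker_ids <- unique(as.character(reactions$marker_id))
  marker_ids <- as.character(marker_ids)
  if (anyDuplicated(marker_ids)) stop("duplicated marker ids")
  missing_m <- setdiff(as.character(reactions$marker_id), marker_ids)
  if (length(missing_m))
    stop("reaction marker(s) not in marker_ids: ", paste(missing_m, collapse = ", "))

  rx <- data.frame(marker_id = as.character(reactions$marker_id),
                   stringsAsFactors = FALSE)
  rx$produces <- prod
  rx$consumes <- cons
  structure(list(metabolites = metabolites, reactions = rx,
                 marker_ids = marker_ids),
            class = "metabolic_graph")
}

#' @export
print.metabolic_graph <- function(x, ...) {
  n_int <- sum(x$metabolites$status == "intracellular")
  cat("Metabolic graph:", nrow(x$metabolites), "metabolites (",
      n_int, "intracellular,", nrow(x$metabolites) - n_int, "extracellular ),",
      nrow(x$reactions), "reaction records,",
      length(x$marker_ids), "markers\n")
  invisible(x)
}

#' Signed incidence matrices of a metabolic graph
#'
#' Builds the m_int-by-r matrix `Q` over intracellular metabolites only:
#' `Q[m, j] = +1` if the reaction of marker j produces metabolite m, `-1` if
#' it consumes m, 0 otherwise; `Q = Q_plus - Q_minus` with both parts
#' non-negative. Markers with no reaction give all-zero columns.
#'
#' @param graph a [metabolic_graph()].
#' @return list with integer matrices `Q`, `Q_plus`, `Q_minus`
#'   (rows = intracellular metabolite ids, columns = marker ids).
#' @export
incidence_matrices <- function(graph) {
  stopifnot(inherits(graph, "metabolic_graph"))
  intra <- graph$metabolites$id[graph$metabolites$status == "intracellular"]
  r <- length(graph$marker_ids)
  Qp <- matrix(0L, length(intra), r, dimnames = list(intra, graph$marker_ids))
  Qm <- Qp
  for (i in seq_len(nrow(graph$reactions))) {
    j <- graph$reactions$marker_id[i]
    for (m in intersect(graph$reactions$produces[[i]], intra)) Qp[m, j] <- 1L
    for (m in intersect(graph$reactions$consumes[[i]], intra)) Qm[m, j] <- 1L
  }
  list(Q = Qp - Qm, Q_plus = Qp, Q_minus = Qm)
}

#' Read / write a metabolic graph as JSON
#'
#' The JSON file holds two tables: `metabolites` (id, status, optional
#' specific flag) and `reactions` (marker_id, comma-separated produces and
#' consumes), plus an optional `marker_ids` vector for markers without
#' reactions.
#'
#' @param file path to a JSON file.
#' @rdname graph_io
#' @export
read_metabolic_graph <- function(file) {
  obj <- jsonlite::fromJSON(file, simplifyDataFrame = TRUE)
  metabolic_graph(obj$metabolites, obj$reactions,
                  marker_ids = obj$marker_ids)
}

#' @param graph graph to write.
#' @rdname graph_io
#' @export
write_metabolic_graph <- function(graph, file) {
  rx <- data.frame(marker_id = graph$reactions$marker_id,
                   produces = vapply(graph$reactions$produces, paste, "", collapse = ","),
                   consumes = vapply(graph$reactions$consumes, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  jsonlite::write_json(list(metabolites = graph$metabolites,
                            reactions = rx,
                            marker_ids = graph$marker_ids),
                       file, auto_unbox = FALSE, pretty = TRUE)
  invisible(file)
}

#' Validate / read a genome panel
#'
#' A genome panel is a genomes-by-markers matrix of integer marker copy
#' counts used to calibrate the constraint bounds. Columns must align with
#' the marker ids of the metabolic graph / abundance matrix.
#'
#' @param x matrix or data.frame of non-negative integer counts.
#' @param genome_ids,marker_ids optional dimname overrides.
#' @return integer matrix with dimnames.
#' @export
genome_panel <- function(x, genome_ids = NULL, marker_ids = NULL) {
  G <- as.matrix(x)
  if (anyNA(G) || any(G < 0)) stop("genome panel must be non-negative")
  if (any(G != round(G))) stop("genome panel must contain integer copy counts")
  storage.mode(G) <- "integer"
  if (!is.null(genome_ids)) rownames(G) <- genome_ids
  if (!is.null(marker_ids)) colnames(G) <- marker_ids
  if (is.null(rownames(G))) rownames(G) <- paste0("genome_", seq_len(nrow(G)))
  if (is.null(colnames(G))) stop("genome panel needs marker column names")
  G
}

#' @param file path to a TSV (rows = genome ids, columns = marker ids).
#' @rdname genome_panel
#' @export
read_genome_panel <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  genome_panel(as.matrix(df[, -1L, drop = FALSE]), genome_ids = ids)
}
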