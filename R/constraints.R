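#' Thresholds and calibration options for constraint building
#'
#' Classification of each intracellular metabolite is driven by the fraction
#' of panel genomes violating the production/consumption hypothesis on a
#' side. The defaults encode "hypothesis holds in more than 95% of genomes"
#' for inclusion and "holds in less than 85%" for exclusion, i.e. violator
#' fractions of 0.05 and 0.15. The bound delta calibrated on the panel is
#' inflated by `multiplier` (the panel under-represents the ecosystem) and
#' optionally rounded up to a multiple of `rounding_step`.
#'
#' Three named presets mirror the calibration options explored in the
#' sensitivity analysis: `"strict"` (multiplier 1, no rounding),
#' `"standard"` (multiplier 1.5, round to 5) and `"loose"` (multiplier 2,
#' round to 5).
#'
#' @param include_frac maximum violator fraction for automatic inclusion.
#' @param exclude_frac violator fraction above which the side is excluded;
#'   fractions in `(include_frac, exclude_frac]` form the gray zone resolved
#'   by the specificity flag.
#' @param multiplier multiplicative compensation factor applied to the
#'   panel-calibrated bound (>= 1).
#' @param rounding_step round the inflated bound up to a multiple of this
#'   value; `NULL` disables rounding.
#' @param preset optional name of a delta-calibration preset overriding
#'   `multiplier`/`rounding_step`.
#' @return a list of class `"caft_thresholds"`.
#' @export
caft_thresholds <- function(include_frac = 0.05, exclude_frac = 0.15,
                            multiplier = 1.5, rounding_step = 5,
                            preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("strict", "standard", "loose"))
    opts <- switch(preset,
                   strict = list(1, NULL),
                   standard = list(1.5, 5),
                   loose = list(2, 5))
    multiplier <- opts[[1L]]
    rounding_step <- opts[[2L]]
  }
  stopifnot(include_frac >= 0, include_frac <= exclude_frac, exclude_frac <= 1,
            multiplier >= 1, is.null(rounding_step) || rounding_step > 0)
  structure(list(include_frac = include_frac, exclude_frac = exclude_frac,
                 multiplier = multiplier, rounding_step = rounding_step),
            class = "caft_thresholds")
}

#' Production/consumption marker loads per genome and metabolite
#'
#' For each panel genome x and intracellular metabolite m, counts the copies
#' of markers whose reactions produce m (`N_prod = Q_plus[m, ] %*% n_x`) and
#' consume m (`N_cons = Q_minus[m, ] %*% n_x`).
#'
#' @param panel genomes-by-markers integer matrix (see [genome_panel()]).
#' @param inc incidence matrices from [incidence_matrices()].
#' @return list with integer matrices `N_prod`, `N_cons`
#'   (genomes x intracellular metabolites).
#' @export
metabolite_loads <- function(panel, inc) {
  if (!identical(colnames(panel), colnames(inc$Q_plus)))
    stop("genome panel columns are not aligned with incidence marker columns")
  list(N_prod = panel %*% t(inc$Q_plus),
       N_cons = panel %*% t(inc$Q_minus))
}

#' Classify one metabolite side against the genome panel
#'
#' A genome violates the production-bounded-by-consumption hypothesis
#' (side 1) when it carries producing markers but no consuming marker
#' (`N_cons = 0`, `N_prod > 0`); genomes with both loads zero satisfy the
#' hypothesis with ratio 0. Side 2 swaps the roles. Membership follows the
#' empirical rules: violator fraction at most `include_frac` includes the
#' metabolite (Rule 1); above `exclude_frac` excludes it (Rule 2); in the
#' gray zone between the two, a metabolite flagged as specific to the process
#' is held in the pending set S (Rule 3) and resolved across the two sides by
#' Rule 4 (pending on one side only: included on that side; pending on both:
#' included in neither); an unflagged or unannotated gray-zone metabolite is
#' excluded, the latter labelled "unresolved".
#'
#' @param N_bounded,N_bounding per-genome loads for the bounded side (the
#'   left-hand side of the inequality) and the bounding side.
#' @param thresholds a [caft_thresholds()] object.
#' @param specific optional logical specificity flag (Rule 3).
#' @return list with `n_violators`, `frac`, `status` (one of `"include"`,
#'   `"exclude"`, `"pending"`) and `rule` label.
#' @export
classify_metabolite_side <- function(N_bounded, N_bounding, thresholds,
                                     specific = NA) {
  stopifnot(length(N_bounded) == length(N_bounding), length(N_bounded) >= 1L)
  viol <- N_bounding == 0 & N_bounded > 0
  frac <- mean(viol)
  if (frac <= thresholds$include_frac) {
    status <- "include"; rule <- "rule1"
  } else if (frac > thresholds$exclude_frac) {
    status <- "exclude"; rule <- "rule2"
  } else if (isTRUE(specific)) {
    status <- "pending"; rule <- "rule3"
  } else if (is.na(specific)) {
    status <- "exclude"; rule <- "rule3-unresolved"
  } else {
    status <- "exclude"; rule <- "rule3"
  }
  list(n_violators = sum(viol), frac = frac, status = status, rule = rule)
}

#' Calibrate the bound delta for one metabolite side
#'
#' Over the admissible genomes (those expressing the bounding side,
#' `N_bounding > 0`), takes the maximum ratio `N_bounded / N_bounding`
#' (genomes with both loads zero contribute 0), inflates it by the
#' compensation `multiplier` and optionally rounds up to a multiple of
#' `rounding_step`.
#'
#' @inheritParams classify_metabolite_side
#' @param thresholds a [caft_thresholds()] object.
#' @return list with `delta_raw` (the pre-factor maximum ratio) and `delta`
#'   (the calibrated bound).
#' @export
compute_delta <- function(N_bounded, N_bounding, thresholds = caft_thresholds()) {
  adm <- N_bounding > 0
  if (!any(adm)) stop("no genome expresses the bounding side; delta undefined")
  ratio <- ifelse(N_bounding > 0, N_bounded / N_bounding, 0)
  delta_raw <- max(ratio)
  delta <- thresholds$multiplier * delta_raw
  if (!is.null(thresholds$rounding_step))
    delta <- thresholds$rounding_step * ceiling(delta / thresholds$rounding_step)
  list(delta_raw = delta_raw, delta = delta)
}

#' Build trait constraints from a metabolic graph and a genome panel
#'
#' Full constraint-construction pipeline: incidence matrices, per-genome
#' metabolite loads, rule-based classification of every intracellular
#' metabolite into the production-bounded set M1 and/or the
#' consumption-bounded set M2, calibration of the bounds, and assembly of the
#' stacked constraint matrix `F_delta` such that feasible trait matrices
#' satisfy `F_delta %*% t(H) <= 0`. The row for metabolite m in M1 is
#' `Q_plus[m, ] - delta1_m * Q_minus[m, ]`; in M2 it is
#' `Q_minus[m, ] - delta2_m * Q_plus[m, ]`.
#'
#' A side whose calibrated pre-factor bound is exactly 0 would force the
#' bounded markers to vanish in every trait; such degenerate sides are
#' dropped and labelled `"degenerate"` in the report. Metabolites named in
#' `force_exclude` are removed from both sets (expertise override).
#'
#' @param graph a [metabolic_graph()].
#' @param panel a [genome_panel()] aligned with the graph's markers.
#' @param thresholds a [caft_thresholds()] object.
#' @param force_exclude character vector of metabolite ids excluded from both
#'   sides by expert decision.
#' @return an object of class `"caft_constraints"`: list with `F_delta`
#'   (rows labelled `"metabolite:side"`), `M1`, `M2`, `delta1`, `delta2`,
#'   `report` (per metabolite and side: violator counts, fractions, rule,
#'   membership, bounds) and `marker_ids`.
#' @export
build_constraints <- function(graph, panel, thresholds = caft_thresholds(),
                              force_exclude = character(0)) {
  inc <- incidence_matrices(graph)
  panel <- panel[, graph$marker_ids, drop = FALSE]
  loads <- metabolite_loads(panel, inc)
  intra <- rownames(inc$Q)
  meta <- graph$metabolites
  specificity_flags <- stats::setNames(meta$specific, meta$id)

  rows <- list(); report <- list()
  status <- matrix("", length(intra), 2L, dimnames = list(intra, c("1", "2")))
  delta1 <- c(); delta2 <- c()
  cls <- list()
  for (m in intra) {
    Np <- loads$N_prod[, m]; Nc <- loads$N_cons[, m]
    cls[[m]] <- list(
      classify_metabolite_side(Np, Nc, thresholds, specificity_flags[[m]]),  # side 1
      classify_metabolite_side(Nc, Np, thresholds, specificity_flags[[m]]))  # side 2
    status[m, ] <- c(cls[[m]][[1L]]$status, cls[[m]][[2L]]$status)
  }
  # Rule 4: resolve gray-zone pendings across sides
  for (m in intra) {
    p1 <- status[m, 1L] == "pending"; p2 <- status[m, 2L] == "pending"
    if (p1 && p2) {
      status[m, ] <- "exclude"
      cls[[m]][[1L]]$rule <- cls[[m]][[2L]]$rule <- "rule4"
    } else if (p1) {
      status[m, 1L] <- "include"; cls[[m]][[1L]]$rule <- "rule4"
    } else if (p2) {
      status[m, 2L] <- "include"; cls[[m]][[2L]]$rule <- "rule4"
    }
  }
  for (m in intersect(force_exclude, intra)) {
    status[m, ] <- "exclude"
    cls[[m]][[1L]]$rule <- cls[[m]][[2L]]$rule <- "expertise"
  }

  for (m in intra) {
    Np <- loads$N_prod[, m]; Nc <- loads$N_cons[, m]
    for (side in 1:2) {
      ci <- cls[[m]][[side]]
      delta_raw <- NA_real_; delta <- NA_real_
      if (status[m, side] == "include") {
        bounded  <- if (side == 1L) Np else Nc
        bounding <- if (side == 1L) Nc else Np
        if (!any(bounding > 0)) {
          status[m, side] <- "exclude"; ci$rule <- "degenerate"
        } else {
          d <- compute_delta(bounded, bounding, thresholds)
          if (d$delta_raw == 0) {
            status[m, side] <- "exclude"; ci$rule <- "degenerate"
          } else {
            delta_raw <- d$delta_raw; delta <- d$delta
            if (side == 1L) {
              delta1[m] <- delta
              rows[[paste0(m, ":1")]] <- inc$Q_plus[m, ] - delta * inc$Q_minus[m, ]
            } else {
              delta2[m] <- delta
              rows[[paste0(m, ":2")]] <- inc$Q_minus[m, ] - delta * inc$Q_plus[m, ]
            }
          }
        }
      }
      report[[paste0(m, ":", side)]] <- data.frame(
        metabolite = m, side = side,
        n_violators = ci$n_violators, violator_frac = ci$frac,
        rule = ci$rule, included = status[m, side] == "include",
        delta_raw = delta_raw, delta = delta,
        stringsAsFactors = FALSE)
    }
  }
  F_delta <- if (length(rows)) do.call(rbind, rows) else
    matrix(0, 0L, length(graph$marker_ids),
           dimnames = list(NULL, graph$marker_ids))
  report <- do.call(rbind, c(report, list(make.row.names = FALSE)))
  structure(list(F_delta = F_delta,
                 M1 = sub(":1$", "", grep(":1$", rownames(F_delta), value = TRUE)),
                 M2 = sub(":2$", "", grep(":2$", rownames(F_delta), value = TRUE)),
                 delta1 = delta1, delta2 = delta2,
                 report = report, marker_ids = graph$marker_ids,
                 thresholds = thresholds),
            class = "caft_constraints")
}

#' Assemble a constraint set from explicit memberships and bounds
#'
#' Lower-level companion to [build_constraints()] for callers who have
#' already decided memberships and bounds: stacks
#' `Q_plus[m, ] - delta1_m * Q_minus[m, ]` rows for `m` in `M1` and
#' `Q_minus[m, ] - delta2_m * Q_plus[m, ]` rows for `m` in `M2`.
#'
#' @param inc incidence matrices from [incidence_matrices()].
#' @param M1,M2 character vectors of intracellular metabolite ids.
#' @param delta1,delta2 named numeric vectors of positive bounds covering
#'   `M1` and `M2`.
#' @return a `"caft_constraints"` object (without a classification report).
#' @export
assemble_constraints <- function(inc, M1, M2, delta1, delta2) {
  stopifnot(all(M1 %in% rownames(inc$Q)), all(M2 %in% rownames(inc$Q)),
            all(M1 %in% names(delta1)), all(M2 %in% names(delta2)),
            all(delta1[M1] > 0), all(delta2[M2] > 0))
  rows <- list()
  for (m in M1)
    rows[[paste0(m, ":1")]] <- inc$Q_plus[m, ] - delta1[[m]] * inc$Q_minus[m, ]
  for (m in M2)
    rows[[paste0(m, ":2")]] <- inc$Q_minus[m, ] - delta2[[m]] * inc$Q_plus[m, ]
  F_delta <- if (length(rows)) do.call(rbind, rows) else
    matrix(0, 0L, ncol(inc$Q), dimnames = list(NULL, colnames(inc$Q)))
  structure(list(F_delta = F_delta, M1 = M1, M2 = M2,
                 delta1 = delta1[M1], delta2 = delta2[M2],
                 report = NULL, marker_ids = colnames(inc$Q),
                 thresholds = NULL),
            class = "caft_constraints")
}

#' @export
print.caft_constraints <- function(x, ...) {
  cat("CAFT constraint set:", nrow(x$F_delta), "constraints on",
      ncol(x$F_delta), "markers\n")
  cat("  production bounded by consumption (M1):", length(x$M1), "metabolites\n")
  cat("  consumption bounded by production (M2):", length(x$M2), "metabolites\n")
  invisible(x)
}

#' Rescale a constraint matrix to the column-scaled trait space
#'
#' Returns `F_delta %*% diag(D)` so that `F_delta %*% t(H)` equals
#' `F_scaled %*% t(H_scaled)` for paired unscaled/scaled trait matrices.
#'
#' @param cs a `"caft_constraints"` object or a bare constraint matrix.
#' @param D per-marker scaling vector, aligned with the constraint columns.
#' @return a matrix (bare input) or the constraint object with an extra
#'   `F_scaled` element.
#' @export
scale_constraints <- function(cs, D) {
  FD <- if (inherits(cs, "caft_constraints")) cs$F_delta else as.matrix(cs)
  if (ncol(FD) != length(D))
    stop("scaling vector length does not match constraint columns")
  Fs <- sweep(FD, 2L, D, "*")
  if (inherits(cs, "caft_constraints")) {
    cs$F_scaled <- Fs
    cs
  } else Fs
}

#' Check a trait matrix against a constraint set
#'
#' Evaluates `F_delta %*% t(H)` and reports, per constraint row, the largest
#' slack over traits; the matrix is feasible when every slack is at most
#' `tol`.
#'
#' @param H trait matrix (k traits x r markers), on the same scale as the
#'   constraint matrix used.
#' @param cs a `"caft_constraints"` object or constraint matrix.
#' @param tol feasibility tolerance.
#' @return list with `feasible` (logical), `max_violation`, and `slack`
#'   (constraint rows x traits matrix of constraint values).
#' @export
check_feasibility <- function(H, cs, tol = 1e-8) {
  FD <- if (inherits(cs, "caft_constraints")) cs$F_delta else as.matrix(cs)
  H <- as.matrix(H)
  if (ncol(FD) != ncol(H)) stop("constraint and trait columns do not match")
  slack <- FD %*% t(H)
  mv <- if (length(slack)) max(slack) else -Inf
  list(feasible = mv <= tol, max_violation = mv, slack = slack)
}

#' Write a constraint matrix and its classification report as TSV
#'
#' @param cs a `"caft_constraints"` object.
#' @param file path for the constraint matrix TSV (row labels
#'   `"metabolite:side"`); the report, when present, is written next to it
#'   with suffix `"_report.tsv"`.
#' @export
write_constraints <- function(cs, file) {
  df <- data.frame(constraint = rownames(cs$F_delta), cs$F_delta,
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cs$report)) {
    rf <- sub("(\\.tsv)?$", "_report.tsv", file)
    utils::write.table(cs$report, rf, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}
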