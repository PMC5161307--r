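#' Toy fixture: two planted CAFTs on a five-reaction metabolic graph
#'
#' A fully in-package benchmark: five functional markers `a`-`e` catalyzing
#' the reactions `a: U -> V`, `b: V -> X`, `c: X -> Y`, `d: V -> Z`,
#' `e: U -> T`, with `U`, `Z`, `T` extracellular and `V`, `X`, `Y`
#' intracellular. The planted trait matrix has one trait expressing all five
#' markers equally and one expressing only `a`, `d`, `e` (zeros at `b` and
#' `c`). Three reference genomes with marker copy vectors `(1,1,1,0,0)`,
#' `(1,0,0,1,0)` and `(0,0,0,0,1)` calibrate the constraints; with violator
#' tolerance 0, compensation multiplier 2 and no rounding, the pipeline
#' yields four constraints: `h_a <= 2 (h_b + h_d)`, `h_b <= 2 h_c`,
#' `h_b + h_d <= 2 h_a`, `h_c <= 2 h_b`, and metabolite `Y` drops out of
#' both sets.
#'
#' @return list with `H_true` (2 x 5), `graph` (a [metabolic_graph()]),
#'   `genomes` (3 x 5 [genome_panel()]), `marker_ids`, and `thresholds`
#'   (the zero-tolerance, multiplier-2, no-rounding [caft_thresholds()]
#'   matching the small panel).
#' @export
toy_fixture <- function() {
  markers <- c("a", "b", "c", "d", "e")
  H_true <- matrix(c(1, 1, 1, 1, 1,
                     1, 0, 0, 1, 1), 2L, 5L, byrow = TRUE,
                   dimnames = list(c("CAFT_1", "CAFT_2"), markers))
  metabolites <- data.frame(
    id = c("U", "V", "X", "Y", "Z", "T"),
    status = c("extracellular", "intracellular", "intracellular",
               "intracellular", "extracellular", "extracellular"),
    stringsAsFactors = FALSE)
  reactions <- data.frame(
    marker_id = markers,
    produces = c("V", "X", "Y", "Z", "T"),
    consumes = c("U", "V", "X", "V", "U"),
    stringsAsFactors = FALSE)
  graph <- metabolic_graph(metabolites, reactions, marker_ids = markers)
  genomes <- genome_panel(matrix(c(1, 1, 1, 0, 0,
                                   1, 0, 0, 1, 0,
                                   0, 0, 0, 0, 1), 3L, 5L, byrow = TRUE,
                                 dimnames = list(paste0("x", 1:3), markers)))
  list(H_true = H_true, graph = graph, genomes = genomes,
       marker_ids = markers,
       thresholds = caft_thresholds(include_frac = 0, exclude_frac = 0,
                                    multiplier = 2, rounding_step = NULL))
}

#' Simulate abundance samples from planted traits
#'
#' Draws a weight matrix with entries uniform on (0, 1), forms the noiseless
#' mixture `B = W_true %*% H_true`, and perturbs it with multiplicative
#' Gaussian noise `a_ij = b_ij * (1 + noise * eps_ij)` with standard normal
#' `eps`. Entries driven negative by the noise (essentially impossible at
#' noise 0.2) are clipped to zero and counted.
#'
#' @param n number of samples.
#' @param H_true planted trait matrix (defaults to the toy fixture's).
#' @param noise multiplicative noise level (>= 0).
#' @param seed optional integer seed.
#' @param weight_fn generator for the weight entries, called as
#'   `weight_fn(n * k)`.
#' @return list with `A` (abundance matrix), `W_true`, `H_true`,
#'   `n_clipped`.
#' @export
simulate_caft_samples <- function(n = 80L, H_true = toy_fixture()$H_true,
                                  noise = 0.2, seed = NULL,
                                  weight_fn = stats::runif) {
  stopifnot(n >= 1L, noise >= 0, all(H_true >= 0))
  H_true <- as.matrix(H_true)
  k <- nrow(H_true)
  if (!is.null(seed)) set.seed(as.integer(seed))
  W <- matrix(weight_fn(n * k), n, k)
  B <- W %*% H_true
  A <- B * (1 + noise * stats::rnorm(length(B)))
  n_clipped <- sum(A < 0)
  A <- pmax(A, 0)
  rownames(A) <- rownames(W) <- paste0("sample_", seq_len(n))
  colnames(A) <- colnames(H_true)
  colnames(W) <- rownames(H_true)
  list(A = A, W_true = W, H_true = H_true, n_clipped = n_clipped)
}

#' Simulate a feasible planted trait matrix
#'
#' Utility for solver property tests: draws non-negative trait matrices
#' entrywise uniform and, when a constraint set is supplied, rejects draws
#' until `F_delta %*% t(H) <= 0` holds, yielding feasible-by-construction
#' planted traits. A `sparsity` fraction of entries is zeroed before the
#' feasibility check to plant marker-sparse traits.
#'
#' @param k,r dimensions.
#' @param constraints optional `"caft_constraints"` object or matrix.
#' @param sparsity fraction of entries set to zero.
#' @param max_tries rejection cap.
#' @param seed optional seed.
#' @return a k x r non-negative (feasible) matrix.
#' @export
simulate_planted_traits <- function(k, r, constraints = NULL, sparsity = 0,
                                    max_tries = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  FD <- if (is.null(constraints)) NULL else
    if (inherits(constraints, "caft_constraints")) constraints$F_delta
    else as.matrix(constraints)
  for (i in seq_len(max_tries)) {
    H <- matrix(stats::runif(k * r), k, r)
    if (sparsity > 0)
      H[sample(length(H), round(sparsity * length(H)))] <- 0
    if (is.null(FD) || all(FD %*% t(H) <= 0)) {
      if (!is.null(FD)) colnames(H) <- colnames(FD)
      return(H)
    }
  }
  stop("no feasible draw in ", max_tries, " tries; constraints too tight")
}
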