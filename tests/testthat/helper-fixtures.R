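# Shared fixtures: the planted two-trait toy benchmark and a tight solver
# control for subproblem-accuracy checks.

toy <- toy_fixture()
toy_cs <- build_constraints(toy$graph, toy$genomes, toy$thresholds)

tight_control <- caft_control(inner_max = 3000L, inner_tol = 1e-13,
                              uzawa_max = 300L, al_tol = 1e-8,
                              max_outer = 400L, tol_outer = 1e-12)

random_abundance <- function(n, r, seed) {
  set.seed(seed)
  abundance_matrix(matrix(stats::runif(n * r, 0.1, 2), n, r))
}
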