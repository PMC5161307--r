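test_that("metabolite loads reproduce the toy genome bookkeeping", {
  inc <- incidence_matrices(toy$graph)
  loads <- metabolite_loads(toy$genomes, inc)
  expect_equal(loads$N_prod["x1", "V"], 1L, ignore_attr = TRUE)
  expect_equal(loads$N_cons["x1", "V"], 1L, ignore_attr = TRUE)  # n1b + n1d
  expect_equal(loads$N_prod["x3", "V"], 0L, ignore_attr = TRUE)
  expect_equal(loads$N_cons["x3", "V"], 0L, ignore_attr = TRUE)
  zero <- genome_panel(matrix(0L, 1, 5, dimnames = list("z", toy$marker_ids)))
  lz <- metabolite_loads(zero, inc)
  expect_true(all(lz$N_prod == 0) && all(lz$N_cons == 0))
  bad <- toy$genomes[, 5:1]
  expect_error(metabolite_loads(bad, inc), "aligned")
})

test_that("metabolite classification follows the violator-fraction rules", {
  th <- caft_thresholds(include_frac = 0.05, exclude_frac = 0.15)
  # 0 violators in 190 -> include
  c1 <- classify_metabolite_side(rep(1L, 190), rep(1L, 190), th)
  expect_equal(c1$status, "include"); expect_equal(c1$rule, "rule1")
  # 68 of 190 genomes consume nothing while producing -> exclude (Rule 2)
  Nb <- rep(1L, 190); Ng <- c(rep(0L, 68), rep(1L, 122))
  c2 <- classify_metabolite_side(Nb, Ng, th)
  expect_equal(c2$n_violators, 68L)
  expect_equal(c2$status, "exclude"); expect_equal(c2$rule, "rule2")
  # both-zero genomes satisfy the hypothesis (ratio-0 convention)
  c3 <- classify_metabolite_side(c(1L, 1L, 0L), c(1L, 1L, 0L),
                                 caft_thresholds(0, 0))
  expect_equal(c3$status, "include")
  # gray zone: specificity flag decides
  Ng <- c(rep(0L, 19), rep(1L, 171))   # 10% violators
  expect_equal(classify_metabolite_side(Nb, Ng, th, specific = TRUE)$status,
               "pending")
  expect_equal(classify_metabolite_side(Nb, Ng, th, specific = FALSE)$status,
               "exclude")
  un <- classify_metabolite_side(Nb, Ng, th, specific = NA)
  expect_equal(un$status, "exclude")
  expect_match(un$rule, "unresolved")
})

test_that("delta calibration multiplies, rounds up and ignores genome order", {
  th <- caft_thresholds(multiplier = 1.5, rounding_step = 5)
  d <- compute_delta(c(17L, 3L), c(1L, 2L), th)   # max ratio 17.3? use 17/1
  expect_equal(d$delta_raw, 17)
  expect_equal(d$delta, 5 * ceiling(1.5 * 17 / 5))
  expect_equal(compute_delta(1L, 1L, th)$delta, 5)   # smallest bucket
  expect_equal(compute_delta(1L, 1L,
                             caft_thresholds(multiplier = 2,
                                             rounding_step = NULL))$delta, 2)
  # 1.5 * 17.3 = 25.95 -> 30
  expect_equal(compute_delta(c(173L), c(10L), th)$delta, 30)
  # order and duplication invariance
  Nb <- c(3L, 7L, 0L); Ng <- c(2L, 2L, 0L)
  d0 <- compute_delta(Nb, Ng, th)
  expect_equal(compute_delta(rev(Nb), rev(Ng), th), d0)
  expect_equal(compute_delta(c(Nb, Nb[2]), c(Ng, Ng[2]), th), d0)
  expect_error(compute_delta(c(1L, 2L), c(0L, 0L), th), "no genome")
})

test_that("toy pipeline reproduces the four printed inequalities exactly", {
  FD <- toy_cs$F_delta
  expect_equal(nrow(FD), 4L)
  expect_equal(FD["V:1", ], c(a = 1, b = -2, c = 0, d = -2, e = 0))
  expect_equal(FD["X:1", ], c(a = 0, b = 1, c = -2, d = 0, e = 0))
  expect_equal(FD["V:2", ], c(a = -2, b = 1, c = 0, d = 1, e = 0))
  expect_equal(FD["X:2", ], c(a = 0, b = -2, c = 1, d = 0, e = 0))
  expect_setequal(toy_cs$M1, c("V", "X"))
  expect_setequal(toy_cs$M2, c("V", "X"))
  # Y: 33% violators on the production side, degenerate on the consumption side
  rep_y <- toy_cs$report[toy_cs$report$metabolite == "Y", ]
  expect_false(any(rep_y$included))
  expect_equal(rep_y$violator_frac[rep_y$side == 1], 1 / 3)
  # the planted truth is feasible
  expect_true(check_feasibility(toy$H_true, toy_cs)$feasible)
})

test_that("assemble_constraints stacks rows from explicit memberships", {
  inc <- incidence_matrices(toy$graph)
  cs <- assemble_constraints(inc, M1 = "V", M2 = c("V", "X"),
                             delta1 = c(V = 2), delta2 = c(V = 2, X = 2))
  expect_equal(nrow(cs$F_delta), 3L)
  expect_equal(cs$F_delta["V:1", "b"], -2, ignore_attr = TRUE)
  cs0 <- assemble_constraints(inc, character(0), character(0),
                              numeric(0), numeric(0))
  expect_equal(nrow(cs0$F_delta), 0L)
})

test_that("scaled constraints are equivalent to unscaled ones", {
  expect_equal(scale_constraints(toy_cs$F_delta, rep(1, 5)), toy_cs$F_delta)
  for (seed in 1:5) {
    set.seed(seed)
    D <- runif(5, 0.5, 3)
    H <- matrix(runif(10), 2, 5)
    H_scaled <- sweep(H, 2L, D, "/")
    Fs <- scale_constraints(toy_cs$F_delta, D)
    expect_equal(toy_cs$F_delta %*% t(H), Fs %*% t(H_scaled),
                 tolerance = 1e-10, ignore_attr = TRUE)
    # feasibility status is preserved under scaling
    expect_equal(max(toy_cs$F_delta %*% t(H)) <= 0,
                 max(Fs %*% t(H_scaled)) <= 1e-10)
  }
})

test_that("feasibility checking reports slacks and violations", {
  ck <- check_feasibility(matrix(1, 1, 5), toy_cs)
  expect_true(ck$feasible)
  expect_equal(ck$slack["V:1", 1], 1 - 4, ignore_attr = TRUE)
  bad <- matrix(c(0, 0, 1, 0, 0), 1)
  ck2 <- check_feasibility(bad, toy_cs)  # violates h_c <= 2 h_b
  expect_false(ck2$feasible)
  expect_equal(ck2$max_violation, 1)
})

test_that("membership is monotone in the inclusion threshold", {
  set.seed(42)
  g <- metabolic_graph(
    metabolites = data.frame(id = c("m1", "m2", "m3", "ext"),
                             status = c(rep("intracellular", 3), "extracellular")),
    reactions = data.frame(
      marker_id = c("k1", "k2", "k3", "k4"),
      produces = c("m1", "m2", "m3", "ext"),
      consumes = c("ext", "m1", "m2", "m3")))
  panel <- genome_panel(matrix(rbinom(80, 2, 0.6), 20, 4,
                               dimnames = list(paste0("g", 1:20),
                                               c("k1", "k2", "k3", "k4"))))
  sizes <- sapply(c(0.0, 0.1, 0.25, 0.5), function(f) {
    cs <- build_constraints(g, panel,
                            caft_thresholds(include_frac = f, exclude_frac = f,
                                            multiplier = 1.5, rounding_step = 5))
    length(union(cs$M1, cs$M2))
  })
  expect_true(all(diff(sizes) >= 0))
})

test_that("expertise overrides force metabolites out of both sets", {
  cs <- build_constraints(toy$graph, toy$genomes, toy$thresholds,
                          force_exclude = "V")
  expect_false("V" %in% union(cs$M1, cs$M2))
  expect_true(all(cs$report$rule[cs$report$metabolite == "V"] == "expertise"))
})
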