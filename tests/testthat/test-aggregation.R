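hit <- function(gene, fam, s, e, ev)
  data.frame(gene_id = gene, family = fam, start = s, end = e, e_value = ev,
             stringsAsFactors = FALSE)

test_that("overlap resolution applies the three pairwise rules", {
  # small overlap (8 <= 10% of the 100-residue module): both kept
  h <- rbind(hit("g", "GH13", 1, 100, 1e-20), hit("g", "GH16", 93, 292, 1e-18))
  expect_equal(nrow(resolve_overlaps(h)), 2L)
  # large overlap, e-value ratio 1e40 >= 100: better hit kept
  h <- rbind(hit("g", "GH13", 1, 100, 1e-50), hit("g", "GH16", 51, 250, 1e-10))
  out <- resolve_overlaps(h)
  expect_equal(out$family, "GH13")
  # large overlap, comparable e-values: both discarded
  h <- rbind(hit("g", "GH13", 1, 100, 1e-12), hit("g", "GH16", 51, 250, 1e-11))
  expect_equal(nrow(resolve_overlaps(h)), 0L)
})

test_that("overlap resolution is order-invariant and discards globally", {
  h <- rbind(hit("g", "A", 1, 100, 1e-30),
             hit("g", "B", 50, 150, 1e-29),   # conflicts with A -> both out
             hit("g", "C", 300, 400, 1e-5),
             hit("g2", "D", 1, 50, 1e-3))
  out <- resolve_overlaps(h)
  expect_setequal(out$family, c("C", "D"))
  for (seed in 1:4) {
    set.seed(seed)
    perm <- h[sample(nrow(h)), ]
    expect_setequal(resolve_overlaps(perm)$family, out$family)
  }
})

test_that("overlap resolution validates intervals and e-values", {
  expect_error(resolve_overlaps(hit("g", "A", 10, 5, 1e-3)), "malformed")
  expect_error(resolve_overlaps(hit("g", "A", 1, 5, 0)), "positive")
})

test_that("marker aggregation dispatches multi-marker genes and conserves mass", {
  gf <- matrix(c(0.4, 0.1,
                 0.2, 0.3,
                 0.6, 0.5), 3, 2, byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  ann <- list(g1 = "K00882", g2 = c("K01034", "K01035"), g3 = "K01034")
  A <- aggregate_markers(gf, ann)
  expect_equal(A["s1", "K00882"], 0.4)
  expect_equal(A["s1", "K01034"], 0.1 + 0.6)   # half of g2 plus g3
  expect_equal(A["s1", "K01035"], 0.1)
  # mass conservation per sample
  expect_equal(rowSums(A), colSums(gf), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("merge groups average member totals and validate members", {
  gf <- matrix(c(0.2, 0.4), 2, 1,
               dimnames = list(c("g1", "g2"), "s1"))
  ann <- list(g1 = "K01034", g2 = "K01035")
  A <- aggregate_markers(gf, ann,
                         merge_groups = list("K01034/K01035" = c("K01034", "K01035")))
  expect_equal(unname(A["s1", "K01034/K01035"]), 0.3)
  expect_false("K01034" %in% colnames(A))
  expect_error(aggregate_markers(gf, ann, merge_groups = list(x = "K99999")),
               "unknown marker")
  expect_error(aggregate_markers(gf, list(g1 = character(0))), "empty marker")
})
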