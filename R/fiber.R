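#' Fiber-degradation marker and metabolite catalog
#'
#' The packaged description of the fiber-degradation case study in the human
#' gut microbiota: 25 glycoside hydrolase / pectin lyase families, 61 KEGG
#' orthology markers (one per fermentation reaction, several being merged-KO
#' markers), the 43 metabolites of the sugar-fermentation graph with their
#' intracellular/extracellular status, and the calibrated constraint bounds
#' for the 25 intracellular metabolites (a dash meaning the side is
#' unconstrained). The reaction-to-metabolite edge list of the full
#' fermentation graph is not part of the catalog.
#'
#' @return list with data frames `gh_pl` (family), `ko_markers` (reaction,
#'   marker), `metabolites` (id, status), `delta_table` (metabolite,
#'   delta1, delta2; `NA` = side unconstrained).
#' @export
fiber_catalog <- function() {
  gh_pl <- data.frame(family = c(
    "GH3", "GH5", "GH8", "GH9", "GH10", "GH13", "GH16", "GH26", "GH28",
    "GH30", "GH32", "GH39", "GH43", "GH44", "GH48", "GH51", "GH74", "GH91",
    "GH94", "GH115", "GH120", "GH127", "PL1", "PL9", "PL11"),
    stringsAsFactors = FALSE)
  ko_markers <- data.frame(
    reaction = 1:61,
    marker = c(
      "K01809", "K00882", "K06859", "K01810", "K01803", "K00150", "K00134",
      "K00927", "K00131", "K01834", "K01689", "K00036", "K01057", "K07404",
      "K01690", "K00874", "K00041", "K01685", "K00883", "K00849", "K00965",
      "K01818", "K00879", "K01628", "K01813", "K01804", "K01786", "K03077",
      "K03080", "K00854", "K01621", "K00169/170/171/172", "K00627", "K03737",
      "K00656", "K04020", "K00625", "K00925", "K00626", "K01034/K01035",
      "K00634", "K00929", "K01574", "K01938/K00288/K01491", "K00297",
      "K00004/K03366", "K00016", "K01847", "K01848/K01849", "K01026",
      "K00672", "K01499", "K00319", "K13942", "K00320", "K00577/578/.../584",
      "K00399/K00401/K00402", "K01699/K13919/K13920", "K13922", "K13788",
      "K15024"),
    stringsAsFactors = FALSE)
  metabolites <- data.frame(
    id = c("Acetate", "Acetone", "Butanediol", "Butanoate", "D-galacturonate",
           "D-Xylose", "Formate", "Fructose", "Galactose", "Glucose",
           "Lactate", "L-Arabinose", "L-Fucose", "L-Lactaldehyde",
           "L-Rhamnose", "Mannose", "Methane", "Propanoate",
           "10-Formyltetrahydrofolate", "2-Dehydro-3-deoxy-D-gluconate",
           "5,10-Methenyltetrahydromethanopterin",
           "5,10-Methylenetetrahydromethanopterin",
           "5-Formyl-5,6,7,8-tetrahydromethanopterin",
           "5-Methyl-5,6,7,8-tetrahydromethanopterin",
           "Acetoacetyl-CoA", "Acetyl phosphate", "Acetyl-CoA",
           "Butanoyl phosphate", "D-Altronate", "D-Gluconate 6-phosphate",
           "D-Glucono-1,5-lactone 6-phosphate",
           "Dihydroxyacetone phosphate", "Galactose 1-phosphate",
           "Glyceraldehyde 3-phosphate", "Glycerate 2-phosphate",
           "Glycerate 3-phosphate", "Glycerate1,3 di-phosphate",
           "L-Fuculose", "L-Fuculose 1-phosphate", "L-Ribulose",
           "Methyl-CoM", "Propane 1,2-diol", "Pyruvate"),
    status = c(rep("extracellular", 18L), rep("intracellular", 25L)),
    stringsAsFactors = FALSE)
  delta_table <- data.frame(
    metabolite = c("10-Formyltetrahydrofolate", "2-Dehydro-3-deoxy-D-gluconate",
                   "5,10-Methenyltetrahydromethanopterin",
                   "5,10-Methylenetetrahydromethanopterin",
                   "5-Formyl-5,6,7,8-tetrahydromethanopterin",
                   "Methyl-CoM", "5-Methyl-5,6,7,8-tetrahydromethanopterin",
                   "Acetoacetyl-CoA", "Acetyl-CoA", "Acetyl phosphate",
                   "Butanoyl phosphate", "D-Altronate",
                   "D-Gluconate 6-phosphate", "Glycerate1,3 di-phosphate",
                   "Glyceraldehyde 3-phosphate",
                   "D-Glucono-1,5-lactone 6-phosphate",
                   "Galactose 1-phosphate", "Glycerate 2-phosphate",
                   "Dihydroxyacetone phosphate", "Glycerate 3-phosphate",
                   "L-Fuculose", "L-Fuculose 1-phosphate", "L-Ribulose",
                   "Propane 1,2-diol", "Pyruvate"),
    delta1 = c(5, 5, 5, 5, 5, 5, 5, NA, 20, 10, 5, 10, NA, 5, 30, NA, NA,
               15, 10, 10, 5, NA, 5, NA, 5),
    delta2 = c(20, NA, 5, 5, 5, 5, 5, 5, 5, 10, 5, 10, NA, 5, 5, NA, 10,
               5, 10, 15, 5, NA, NA, NA, 10),
    stringsAsFactors = FALSE)
  list(gh_pl = gh_pl, ko_markers = ko_markers, metabolites = metabolites,
       delta_table = delta_table)
}

#' Constraint bookkeeping of the fiber-degradation catalog
#'
#' Summarizes the calibrated constraint table of [fiber_catalog()]: one
#' constraint per non-missing bound, i.e. metabolites constrained on both
#' sides contribute two rows and one-sided metabolites one row.
#'
#' @return list with `n_constraints`, `n_both`, `n_only_M1`, `n_only_M2`,
#'   `n_unconstrained`, `delta_values` (all bounds, sorted), `delta_range`.
#' @export
fiber_constraint_summary <- function() {
  dt <- fiber_catalog()$delta_table
  in1 <- !is.na(dt$delta1); in2 <- !is.na(dt$delta2)
  deltas <- sort(c(dt$delta1[in1], dt$delta2[in2]))
  list(n_constraints = sum(in1) + sum(in2),
       n_both = sum(in1 & in2),
       n_only_M1 = sum(in1 & !in2),
       n_only_M2 = sum(!in1 & in2),
       n_unconstrained = sum(!in1 & !in2),
       delta_values = deltas,
       delta_range = range(deltas))
}
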