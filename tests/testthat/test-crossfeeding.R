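# Build a community_solution-shaped object with prescribed exchange fluxes
# so allocation rules can be checked on exact numbers.
fake_solution <- function(per_strain_by_met, ip = NULL) {
  strains <- sort(unique(unlist(lapply(per_strain_by_met, names))))
  pool_flows <- lapply(names(per_strain_by_met), function(m) {
    per <- per_strain_by_met[[m]]
    net <- sum(per)
    ipm <- if (!is.null(ip) && m %in% names(ip)) ip[[m]] else max(-net, 0)
    list(IP = ipm, EP = net + ipm, per_strain = per)
  })
  names(pool_flows) <- names(per_strain_by_met)
  structure(list(strain_biomass = stats::setNames(rep(1, length(strains)),
                                                  strains),
                 total_biomass = length(strains),
                 fluxes = NULL, pool_flows = pool_flows,
                 objective_value = 1, status = "optimal",
                 scenario = objective_spec("no_limitation")),
            class = "community_solution")
}

test_that("single donor-recipient pairs become one directed edge", {
  sol <- fake_solution(list(X_e = c(A = 10, B = -10)))
  nw <- extract_cross_feeding(sol)
  expect_equal(nrow(nw$edges), 1)
  expect_equal(nw$edges$donor, "A")
  expect_equal(nw$edges$recipient, "B")
  expect_equal(nw$edges$allocated_flux, 10)
  expect_equal(nw$edges$class, "other")
  expect_equal(nw$unidirectional_donors, "A")
})

test_that("multiple donors are allocated proportionally to their fluxes", {
  sol <- fake_solution(list(X_e = c(A = 6, B = 4, C = -10)))
  nw <- extract_cross_feeding(sol)
  expect_equal(sort(nw$edges$allocated_flux), c(4, 6))
  ## flux conservation: allocations + unattributed import = uptake
  expect_equal(sum(nw$edges$allocated_flux), 10)
})

test_that("medium import is unattributed supply, never a donor", {
  ## A secretes 4, medium imports 6, B consumes 10: only 4 credited to A
  sol <- fake_solution(list(X_e = c(A = 4, B = -10)), ip = c(X_e = 6))
  nw <- extract_cross_feeding(sol)
  expect_equal(nw$edges$allocated_flux, 4)
})

test_that("sub-threshold fluxes produce no edges", {
  sol <- fake_solution(list(X_e = c(A = 1e-9, B = -1e-9)))
  nw <- extract_cross_feeding(sol)
  expect_equal(nrow(nw$edges), 0)
  expect_length(nw$unidirectional_donors, 0)
  ## non-optimal solutions are rejected
  bad <- fake_solution(list(X_e = c(A = 1, B = -1)))
  bad$status <- "infeasible"
  expect_error(extract_cross_feeding(bad), "optimal")
})

test_that("summary degrees, reciprocity and the potentiator flag", {
  one <- extract_cross_feeding(fake_solution(list(X_e = c(A = 5, B = -5))))
  s <- network_summary(one)
  expect_equal(s$per_strain$out_degree[s$per_strain$strain == "A"], 1)
  expect_equal(s$per_strain$in_degree[s$per_strain$strain == "A"], 0)
  expect_equal(s$per_strain$in_degree[s$per_strain$strain == "B"], 1)

  ## symmetric swap: nobody is a unidirectional donor
  swap <- extract_cross_feeding(fake_solution(list(
    m1_e = c(A = 3, B = -3), m2_e = c(A = -2, B = 2))))
  expect_length(swap$unidirectional_donors, 0)

  ## designed altruist feeding both others, receiving nothing
  alt <- extract_cross_feeding(fake_solution(list(
    vit_e = c(P = 2, A = -1, B = -1), x_e = c(A = 4, B = -4))))
  s2 <- network_summary(alt)
  expect_equal(s2$potentiator_candidates, "P")
})

test_that("per-class counts follow the class map; absent map means other", {
  cmap <- read_class_map()
  sol <- fake_solution(list(vit_e = c(P = 2, A = -2),
                            inter_e = c(A = 3, B = -3),
                            glc_e = c(A = 1, B = -1)))
  nw <- extract_cross_feeding(sol, cmap)
  expect_setequal(nw$edges$class[nw$edges$metabolite == "vit_e"], "vitamin")
  expect_setequal(nw$edges$class[nw$edges$metabolite == "inter_e"],
                  "organic_acid")
  counts <- nw$per_class_counts
  expect_equal(sum(counts$n_metabolites),
               nrow(unique(nw$edges[, c("metabolite", "class",
                                        "donor", "recipient")])))
  ## same topology, all classes collapse to other without a map
  nw0 <- extract_cross_feeding(sol, NULL)
  expect_equal(nw0$edges[, c("metabolite", "donor", "recipient")],
               nw$edges[, c("metabolite", "donor", "recipient")])
  expect_true(all(nw0$edges$class == "other"))
})

test_that("network topology is invariant under strain relabeling", {
  sol <- fake_solution(list(X_e = c(A = 6, B = 4, C = -10)))
  nw <- extract_cross_feeding(sol)
  relabeled <- fake_solution(list(X_e = c(Zeta = 6, Yps = 4, Xi = -10)))
  nw2 <- extract_cross_feeding(relabeled)
  expect_equal(nrow(nw$edges), nrow(nw2$edges))
  expect_equal(sort(nw$edges$allocated_flux), sort(nw2$edges$allocated_flux))
})

test_that("condition comparison finds shared and unique exchanges", {
  n1 <- extract_cross_feeding(fake_solution(list(
    X_e = c(A = 5, B = -5), V_e = c(A = 1, B = -1))))
  n2 <- extract_cross_feeding(fake_solution(list(X_e = c(A = 5, B = -5))))
  cmp <- compare_conditions(list(C1 = n1, C4 = n2))
  expect_equal(cmp$unique_metabolites$C1, "V_e")
  expect_length(cmp$unique_metabolites$C4, 0)
  expect_equal(sum(cmp$counts$n_C1), 2)
  expect_equal(sum(cmp$counts$n_C4), 1)
  ## identical networks: all differences zero
  same <- compare_conditions(list(a = n1, b = n1))
  expect_true(all(same$counts$difference == 0))
  ## mismatched strain sets are rejected
  n3 <- extract_cross_feeding(fake_solution(list(X_e = c(A = 5, Q = -5))))
  expect_error(compare_conditions(list(a = n1, b = n3)), "strain sets")
  expect_error(compare_conditions(list(a = n1)), "two conditions")
})

test_that("richer media reduce obligate cross-feeding on a designed pair", {
  ## P grows to a cap of 2 and can spill surplus carbon as x1; Q converts
  ## x1 at 40% efficiency but the second carbon source at 100%. On c1
  ## alone, Q's only food is spilled x1 (edge present); with c2 available,
  ## parsimonious import favors the direct route and the edge disappears.
  producer <- strain_model(
    "P",
    data.frame(id = c("c1_e", "c1_c", "x1_c", "x1_e"),
               compartment = c("e", "c", "c", "e")),
    data.frame(id = c("EX_c1", "T_c1", "biomass", "SPILL", "T_x1", "EX_x1"),
               lb = c(-1000, 0, 0, 0, 0, 0),
               ub = c(1000, 1000, 2, 1000, 1000, 1000),
               exchange = NA,
               biomass = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)),
    list(EX_c1 = c(c1_e = -1), T_c1 = c(c1_e = -1, c1_c = 1),
         biomass = c(c1_c = -1), SPILL = c(c1_c = -1, x1_c = 1),
         T_x1 = c(x1_c = -1, x1_e = 1), EX_x1 = c(x1_e = -1)))
  consumer <- strain_model(
    "Q",
    data.frame(id = c("x1_e", "x1_c", "c2_e", "c2_c", "carbon_c"),
               compartment = c("e", "c", "e", "c", "c")),
    data.frame(id = c("EX_x1", "T_x1", "CAT_x1", "EX_c2", "T_c2", "CAT_c2",
                      "biomass"),
               lb = c(-1000, 0, 0, -1000, 0, 0, 0),
               ub = c(0, 1000, 1000, 1000, 1000, 1000, 20),
               exchange = NA,
               biomass = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)),
    list(EX_x1 = c(x1_e = -1), T_x1 = c(x1_e = -1, x1_c = 1),
         CAT_x1 = c(x1_c = -1, carbon_c = 0.4),
         EX_c2 = c(c2_e = -1), T_c2 = c(c2_e = -1, c2_c = 1),
         CAT_c2 = c(c2_c = -1, carbon_c = 1),
         biomass = c(carbon_c = -1)))
  pair <- list(producer, consumer)
  poor <- assemble_community(pair, medium(c(c1_e = 10)))
  rich <- assemble_community(pair, medium(c(c1_e = 10, c2_e = 100)))
  nw_poor <- extract_cross_feeding(solve_community_pfba(poor))
  nw_rich <- extract_cross_feeding(solve_community_pfba(rich))
  dep_poor <- sum(nw_poor$edges$metabolite == "x1_e")
  dep_rich <- sum(nw_rich$edges$metabolite == "x1_e")
  expect_gt(dep_poor, 0)
  expect_lt(dep_rich, dep_poor)
})

test_that("exports round-trip through GraphML and edge TSV", {
  sol <- fake_solution(list(vit_e = c(P = 2, A = -1, B = -1),
                            inter_e = c(A = 3, B = -3)))
  nw <- extract_cross_feeding(sol, read_class_map())
  for (fmt in c("graphml", "edge_tsv")) {
    p <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_network(nw, p, fmt)
    back <- import_network(p, fmt, nodes = nw$nodes)
    expect_equal(back$per_class_counts, nw$per_class_counts)
    expect_setequal(back$nodes, nw$nodes)
  }
  ## empty network still exports valid files
  empty <- extract_cross_feeding(fake_solution(list(X_e = c(A = 0, B = 0))))
  p2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(empty, p2)
  expect_equal(nrow(import_network(p2)$edges), 0)
})
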