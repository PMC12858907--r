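oracle_tsv <- function() {
  utils::read.table(test_path("ORACLE.tsv"), header = TRUE, sep = "\t")
}

crossfeeder_community <- function(amount = 10) {
  assemble_community(crossfeeder_pair(), medium(c(glc_e = amount)))
}

test_that("assembly shares pool metabolites and namespaces internals", {
  com <- crossfeeder_community()
  expect_equal(sort(com$pool_metabolites), c("X_e", "glc_e"))
  expect_equal(sum(com$reactions$biomass), 2)
  expect_false(anyDuplicated(com$reactions$id) > 0)
  ## pool balance row exists for every shared metabolite
  expect_true(all(com$pool_metabolites %in% rownames(com$S)))
  ## duplicate ids and non-interacting strains are rejected
  cf <- crossfeeder_pair()
  expect_error(assemble_community(list(cf$A, cf$A), medium()), "duplicate")
  lonely <- strain_model(
    "L", data.frame(id = "m_c", compartment = "c"),
    data.frame(id = c("GEN", "biomass"), lb = 0, ub = 1,
               exchange = FALSE, biomass = c(FALSE, TRUE)),
    list(GEN = c(m_c = 1), biomass = c(m_c = -1)))
  expect_error(assemble_community(list(lonely), medium()), "no exchange")
})

test_that("strains with disjoint exchange metabolites give an additive pool", {
  a <- make_toy_strain("A", c(glc = 10))
  b <- make_toy_strain("B", c(cit = 10))
  com <- assemble_community(list(a, b), medium(c(glc_e = 5, cit_e = 5)))
  expect_equal(length(com$pool_metabolites), 2)
})

test_that("a single-strain community reproduces single-strain FBA", {
  for (seed in c(31, 32, 33)) {
    m <- random_toy_strain(seed)
    med <- medium(stats::setNames(c(9, 4, 2), c("c1_e", "c2_e", "c3_e")))
    single <- solve_fba(m, med)$objective_value
    com <- assemble_community(list(m), med)
    sol <- solve_community(com)
    expect_equal(sol$total_biomass, single, tolerance = 1e-9)
  }
})

test_that("the four scenarios reproduce the frozen fixture optima", {
  ora <- oracle_tsv()
  com <- crossfeeder_community()
  val <- function(q) ora$value[ora$fixture == "crossfeeder_glc10" &
                                 ora$quantity == q]

  s_no <- solve_community(com, objective_spec("no_limitation"))
  expect_equal(s_no$total_biomass, val("no_limitation_total"), tolerance = 1e-8)
  expect_equal(unname(s_no$strain_biomass), c(10, 5), tolerance = 1e-8)

  s_eq <- solve_community(com, objective_spec("equal_abundance"))
  expect_equal(s_eq$objective_value, val("equal_abundance_mu"), tolerance = 1e-8)
  expect_equal(unname(s_eq$strain_biomass), c(5, 5), tolerance = 1e-8)

  s_tb <- solve_community(com, objective_spec("target_strain", target = "B"))
  expect_equal(unname(s_tb$strain_biomass["B"]), val("target_B_biomass"),
               tolerance = 1e-8)
  expect_error(solve_community(com, objective_spec("target_strain",
                                                   target = "nobody")),
               "unknown target")

  s_da <- solve_community(com, objective_spec("defined_abundances",
                                              abundances = c(A = 2/3, B = 1/3)))
  expect_equal(unname(s_da$strain_biomass["A"] / s_da$strain_biomass["B"]), 2,
               tolerance = 1e-6)
})

test_that("infeasible abundance coupling reports zero growth, not an error", {
  ## B cannot grow without A feeding it X; forcing B-heavy composition with
  ## a non-growing partner must yield mu = 0
  cf <- crossfeeder_pair()
  b_only <- assemble_community(cf["B"], medium(c(glc_e = 10)))
  s <- solve_community(b_only, objective_spec("equal_abundance"))
  expect_equal(s$status, "optimal")
  expect_equal(s$total_biomass, 0)
})

test_that("every returned solution balances each pool metabolite", {
  ## Eq-3-style conservation: secretions + import - export - uptakes = 0
  set.seed(77)
  for (seed in 1:10) {
    com <- random_toy_community(300 + seed)$community
    for (sc in list(objective_spec("no_limitation"),
                    objective_spec("equal_abundance"))) {
      sol <- solve_community(com, sc)
      if (sol$status != "optimal" || is.null(sol$fluxes)) next
      expect_lt(max(abs(com$S %*% sol$fluxes)), 1e-6)
      for (m in names(sol$pool_flows)) {
        pf <- sol$pool_flows[[m]]
        expect_lt(abs(sum(pf$per_strain) + pf$IP - pf$EP), 1e-6)
        expect_gte(pf$IP, -1e-9)
        expect_lte(pf$IP, com$pool_import_bounds[[m]] + 1e-9)
        expect_gte(pf$EP, -1e-9)
      }
    }
  }
})

test_that("scenario ordering: coupled equal growth never beats the free sum", {
  for (seed in 41:46) {
    com <- random_toy_community(seed)$community
    K <- length(com$strain_ids)
    mu <- solve_community(com, objective_spec("equal_abundance"))$objective_value
    total <- solve_community(com, objective_spec("no_limitation"))$total_biomass
    expect_lte(K * mu, total + 1e-6)
  }
})

test_that("pFBA keeps the optimum and never imports more than plain FBA", {
  ora <- oracle_tsv()
  com <- crossfeeder_community()
  plain <- solve_community(com)
  pf <- solve_community_pfba(com)
  expect_equal(pf$total_biomass, plain$total_biomass, tolerance = 1e-6)
  expect_lte(total_import(pf), total_import(plain) + 1e-9)
  expect_equal(total_import(pf),
               ora$value[ora$quantity == "pfba_min_import_at_15"],
               tolerance = 1e-5)

  ## unusable medium components are not imported under pFBA
  t1 <- make_toy_strain("T1", c(glc = 10))
  com2 <- assemble_community(list(t1), medium(c(glc_e = 10, cit_e = 100)))
  ## citrate is not even a pool metabolite (no exchange for it): the pFBA
  ## solution must not import anything beyond the glucose it uses
  pf2 <- solve_community_pfba(com2)
  expect_equal(total_import(pf2), 10, tolerance = 1e-5)

  ## property: over random communities the pFBA import is minimal among
  ## stage-1 optima and the objective is preserved
  for (seed in 51:56) {
    com3 <- random_toy_community(seed)$community
    p3 <- solve_community(com3)
    q3 <- solve_community_pfba(com3)
    expect_equal(q3$total_biomass, p3$total_biomass,
                 tolerance = 1e-6 * max(1, p3$total_biomass))
    expect_lte(total_import(q3), total_import(p3) + 1e-6)
  }
})

test_that("pFBA import total is unique even with redundant transporters", {
  ## two equivalent glucose routes: flux split is degenerate, import is not
  mets <- data.frame(id = c("glc_e", "glc_c"), compartment = c("e", "c"))
  rxns <- data.frame(id = c("EX_glc", "T1", "T2", "biomass"),
                     lb = c(-10, 0, 0, 0), ub = c(1000, 1000, 1000, 1000),
                     exchange = NA, biomass = c(FALSE, FALSE, FALSE, TRUE))
  st <- list(EX_glc = c(glc_e = -1), T1 = c(glc_e = -1, glc_c = 1),
             T2 = c(glc_e = -1, glc_c = 1), biomass = c(glc_c = -1))
  m <- strain_model("R", mets, rxns, st)
  com <- assemble_community(list(m), medium(c(glc_e = 10)))
  pf <- solve_community_pfba(com)
  o <- oracle_min_import(com, pf$total_biomass - 1e-9)
  expect_equal(total_import(pf), o$objective, tolerance = 1e-5)
})

test_that("classic pFBA minimizes total absolute flux at the same optimum", {
  com <- crossfeeder_community()
  cl <- solve_community_pfba(com, classic = TRUE)
  pf <- solve_community_pfba(com)
  expect_equal(cl$total_biomass, pf$total_biomass, tolerance = 1e-6)
  expect_lte(sum(abs(cl$fluxes)), sum(abs(pf$fluxes)) + 1e-6)
})

test_that("depletion drains a finite pool at the uptake cap", {
  t1 <- make_toy_strain("T1", c(glc = 10))
  com <- assemble_community(list(t1), medium(c(glc_e = 10)))
  dep <- simulate_depletion(com, dt = 1, vmax = 1, max_steps = 50)
  expect_equal(dep$growth_time, 10)
  expect_equal(unname(dep$cumulative_biomass["T1"]), 10, tolerance = 1e-6)
  expect_equal(dep$stopped_because, "pool_exhausted")
  expect_equal(sum(dep$trajectory$biomass_T1), dep$cumulative_biomass[["T1"]])
  ## remaining pool is non-increasing for a never-secreted metabolite
  expect_true(all(diff(dep$trajectory$pool_glc_e) <= 1e-9))

  ## empty medium: stopped at once with no growth
  com0 <- assemble_community(list(t1), medium(c(glc_e = 0)))
  dep0 <- simulate_depletion(com0)
  expect_equal(dep0$stopped_because, "no_growth")
  expect_equal(sum(dep0$cumulative_biomass), 0)
  expect_equal(dep0$growth_time, 0)

  expect_error(simulate_depletion(com, dt = 0), "dt")
  expect_error(simulate_depletion(com, vmax = -1), "vmax")
})

test_that("halving dt changes cumulative biomass by at most one step", {
  com <- crossfeeder_community()
  d1 <- simulate_depletion(com, dt = 1, vmax = 2, max_steps = 60)
  d2 <- simulate_depletion(com, dt = 0.5, vmax = 2, max_steps = 120)
  step_inc <- max(rowSums(d1$trajectory[, grep("^biomass_",
                                               names(d1$trajectory))]))
  expect_lt(abs(sum(d1$cumulative_biomass) - sum(d2$cumulative_biomass)),
            step_inc + 1e-6)
})

test_that("secreted metabolites return to the pool for later consumers", {
  ## with vmax low, A secretes X faster than B eats it; the pool must carry
  ## the surplus forward so B's cumulative biomass approaches A's half
  com <- crossfeeder_community()
  dep <- simulate_depletion(com, dt = 1, vmax = 1, max_steps = 100)
  expect_gt(dep$cumulative_biomass[["B"]], 0)
  expect_equal(dep$cumulative_biomass[["B"]],
               dep$cumulative_biomass[["A"]] / 2, tolerance = 0.2)
})

test_that("target profile reports per-strain maxima and growth times", {
  com <- crossfeeder_community()
  prof <- max_target_biomass_profile(com, dt = 1, vmax = 5, max_steps = 50)
  expect_equal(prof$strain_id, c("A", "B"))
  expect_equal(prof$biomass[prof$strain_id == "A"], 10, tolerance = 1e-6)
  expect_equal(prof$biomass[prof$strain_id == "B"], 5, tolerance = 1e-6)
  expect_true(all(prof$growth_time > 0))

  ## a strain with no route from the medium gets a zero entry, not an error
  b_only <- assemble_community(crossfeeder_pair()["B"], medium(c(glc_e = 10)))
  prof0 <- max_target_biomass_profile(b_only)
  expect_equal(prof0$biomass, 0)
})

test_that("superset monotonicity holds for unit-weight free-sum objectives", {
  for (seed in 61:64) {
    rc <- random_toy_community(seed, n_strains = 3)
    med <- rc$medium
    sub <- assemble_community(rc$models[1:2], med)
    full <- assemble_community(rc$models, med)
    expect_gte(solve_community(full)$total_biomass,
               solve_community(sub)$total_biomass - 1e-6)
  }
})

test_that("solution JSON export captures biomass and pool flows", {
  com <- crossfeeder_community()
  sol <- solve_community_pfba(com)
  p <- withr::local_tempfile(fileext = ".json")
  write_solution_json(sol, p)
  back <- jsonlite::fromJSON(p)
  expect_equal(back$total_biomass, sol$total_biomass)
  expect_equal(back$strain_biomass$A, unname(sol$strain_biomass["A"]))
  expect_equal(back$pool_flows$X_e$IP, sol$pool_flows$X_e$IP)
})
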