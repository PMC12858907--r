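#' Build a minimal toy strain model
#'
#' Constructs a small (<= 12 reactions) strain model from an ecological
#' description: which extracellular carbon sources the strain takes up,
#' what it secretes per unit biomass, and an optional auxotrophy. Each
#' uptake u gets an exchange \code{EX_u}, a transporter \code{T_u} and a
#' catabolic step into a common internal carbon pool; the single biomass
#' reaction consumes \code{1/biomass_yield} internal carbon (plus the
#' auxotrophic metabolite, if any) and produces the secreted metabolites at
#' their stated yields. Stoichiometries are abstract (not mass balanced) so
#' optima stay hand-computable.
#'
#' @param id strain id.
#' @param uptakes character vector of carbon source ids, or a named numeric
#'   vector giving per-source uptake bounds (default bound 1000).
#' @param secretions named numeric vector: metabolite id -> yield per unit
#'   biomass (may be empty).
#' @param auxotrophy optional named numeric of length 1: metabolite id ->
#'   amount required per unit biomass.
#' @param biomass_yield biomass produced per unit internal carbon; > 0.
#' @param biomass_cap upper bound of the biomass reaction (default 1000);
#'   0 gives a non-growing strain that can still run catalytic conversions.
#' @return a \code{\link{strain_model}}.
#' @export
make_toy_strain <- function(id, uptakes, secretions = numeric(),
                            auxotrophy = NULL, biomass_yield = 1,
                            biomass_cap = 1000) {
  if (biomass_yield <= 0) stop("biomass_yield must be > 0")
  if (is.null(names(uptakes))) {
    uptakes <- stats::setNames(rep(1000, length(uptakes)), uptakes)
  }
  secr <- secretions
  aux <- auxotrophy
  roles <- c(names(uptakes), names(secr), names(aux))
  if (anyDuplicated(roles))
    stop("metabolite with duplicate roles in toy strain '", id, "': ",
         roles[duplicated(roles)][1L])

  mets <- list(); rxns <- list(); stoich <- list()
  add_met <- function(mid, comp) mets[[length(mets) + 1L]] <<-
    data.frame(id = mid, compartment = comp)
  add_rxn <- function(rid, coef, lb, ub, biomass = FALSE) {
    rxns[[length(rxns) + 1L]] <<-
      data.frame(id = rid, lb = lb, ub = ub, exchange = NA, biomass = biomass)
    stoich[[rid]] <<- coef
  }
  add_met("carbon_c", "c")
  for (u in names(uptakes)) {
    add_met(paste0(u, "_e"), "e"); add_met(paste0(u, "_c"), "c")
    add_rxn(paste0("EX_", u), stats::setNames(-1, paste0(u, "_e")),
            -uptakes[[u]], 1000)
    add_rxn(paste0("T_", u),
            stats::setNames(c(-1, 1), paste0(u, c("_e", "_c"))), 0, 1000)
    add_rxn(paste0("CAT_", u),
            stats::setNames(c(-1, 1), c(paste0(u, "_c"), "carbon_c")), 0, 1000)
  }
  bio_coef <- stats::setNames(-1 / biomass_yield, "carbon_c")
  if (!is.null(aux)) {
    a <- names(aux)
    add_met(paste0(a, "_e"), "e"); add_met(paste0(a, "_c"), "c")
    add_rxn(paste0("EX_", a), stats::setNames(-1, paste0(a, "_e")), -1000, 0)
    add_rxn(paste0("T_", a),
            stats::setNames(c(-1, 1), paste0(a, c("_e", "_c"))), 0, 1000)
    bio_coef[paste0(a, "_c")] <- -unname(aux)
  }
  for (s in names(secr)) {
    add_met(paste0(s, "_e"), "e"); add_met(paste0(s, "_c"), "c")
    bio_coef[paste0(s, "_c")] <- unname(secr[s])
    add_rxn(paste0("T_", s),
            stats::setNames(c(-1, 1), paste0(s, c("_c", "_e"))), 0, 1000)
    add_rxn(paste0("EX_", s), stats::setNames(-1, paste0(s, "_e")), 0, 1000)
  }
  add_rxn("biomass", bio_coef, 0, biomass_cap, biomass = TRUE)
  strain_model(id, do.call(rbind, mets), do.call(rbind, rxns), stoich)
}

#' The worked two-strain cross-feeder fixture
#'
#' Strain A takes up glucose and converts it to metabolite X through two
#' routes -- one coupled to biomass (glc -> bioA + X) and one purely
#' catalytic (glc -> X) -- while strain B grows only on X at a cost of two
#' X per unit biomass. On 10 glucose the hand-derived optima are: total
#' biomass 15 under no_limitation (bioA = 10, bioB = 5), a common growth of
#' 5 per strain under equal_abundance, and bioB = 5 when all resources are
#' allocated to B.
#'
#' @return named list of two \code{\link{strain_model}} objects (A, B).
#' @export
crossfeeder_pair <- function() {
  A <- strain_model(
    "A",
    data.frame(id = c("glc_e", "glc_c", "X_c", "X_e"),
               compartment = c("e", "c", "c", "e")),
    data.frame(id = c("EX_glc", "T_glc", "biomass_A", "R_spill", "T_X", "EX_X"),
               lb = c(-1000, 0, 0, 0, 0, 0),
               ub = c(1000, 1000, 1000, 1000, 1000, 1000),
               exchange = NA, biomass = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)),
    list(EX_glc = c(glc_e = -1),
         T_glc = c(glc_e = -1, glc_c = 1),
         biomass_A = c(glc_c = -1, X_c = 1),
         R_spill = c(glc_c = -1, X_c = 1),
         T_X = c(X_c = -1, X_e = 1),
         EX_X = c(X_e = -1)))
  B <- strain_model(
    "B",
    data.frame(id = c("X_e", "X_c"), compartment = c("e", "c")),
    data.frame(id = c("EX_X", "T_X", "biomass_B"),
               lb = c(-1000, 0, 0), ub = c(1000, 1000, 1000),
               exchange = NA, biomass = c(FALSE, FALSE, TRUE)),
    list(EX_X = c(X_e = -1),
         T_X = c(X_e = -1, X_c = 1),
         biomass_B = c(X_c = -2)))
  list(A = A, B = B)
}

#' Specify a degrader/helper/potentiator toy consortium
#'
#' @param n_helpers number of helper strains (1..3).
#' @param n_potentiators number of potentiator strains (0..2).
#' @param bystander add a non-interacting glucose competitor strain.
#' @param carbon_sources carbon source ids for the media series; the first
#'   is the degrader's substrate, later ones feed the extra helpers and
#'   potentiators.
#' @param budget total carbon budget of the media series (mmol/gDW).
#' @param vit_coeff cofactor requirement per unit carbon routed through a
#'   boosted growth pathway.
#' @param seed integer recorded in the spec; consortium construction is
#'   deterministic, the seed is forwarded to downstream randomized tools.
#' @return object of class \code{toy_spec}.
#' @export
dhp_spec <- function(n_helpers = 1, n_potentiators = 1, bystander = FALSE,
                     carbon_sources = c("glc", "cit", "ac", "fum"),
                     budget = 100, vit_coeff = 0.01, seed = 7) {
  stopifnot(n_helpers >= 1, n_helpers <= 3,
            n_potentiators >= 0, n_potentiators <= 2,
            length(carbon_sources) >= 1, budget > 0, vit_coeff > 0)
  structure(list(n_helpers = n_helpers, n_potentiators = n_potentiators,
                 bystander = bystander, carbon_sources = carbon_sources,
                 budget = budget, vit_coeff = vit_coeff, seed = seed),
            class = "toy_spec")
}

## One dual-route consumer: a basic biomass route and a cofactor-boosted
## route with doubled yield. `sources` = named uptake bounds; `secrete`
## optional named yields coupled to biomass (per unit biomass, both routes).
dual_route_strain <- function(id, sources, yield_basic, yield_boost,
                              vit_coeff, secrete = numeric(),
                              aux_source = FALSE) {
  mets <- list(); rxns <- list(); stoich <- list()
  add_met <- function(mid, comp) mets[[length(mets) + 1L]] <<-
    data.frame(id = mid, compartment = comp)
  add_rxn <- function(rid, coef, lb, ub, biomass = FALSE) {
    rxns[[length(rxns) + 1L]] <<-
      data.frame(id = rid, lb = lb, ub = ub, exchange = NA, biomass = biomass)
    stoich[[rid]] <<- coef
  }
  add_met("carbon_c", "c"); add_met("bio_c", "c")
  add_met("vit_e", "e"); add_met("vit_c", "c")
  for (u in names(sources)) {
    add_met(paste0(u, "_e"), "e"); add_met(paste0(u, "_c"), "c")
    add_rxn(paste0("EX_", u), stats::setNames(-1, paste0(u, "_e")),
            -sources[[u]], if (aux_source) 0 else 1000)
    add_rxn(paste0("T_", u),
            stats::setNames(c(-1, 1), paste0(u, c("_e", "_c"))), 0, 1000)
    add_rxn(paste0("CAT_", u),
            stats::setNames(c(-1, 1), c(paste0(u, "_c"), "carbon_c")), 0, 1000)
  }
  add_rxn("EX_vit", c(vit_e = -1), -1000, 0)
  add_rxn("T_vit", c(vit_e = -1, vit_c = 1), 0, 1000)
  add_rxn("GROW_basic", c(carbon_c = -1 / yield_basic, bio_c = 1), 0, 1000)
  add_rxn("GROW_boost", c(carbon_c = -1 / yield_boost,
                          vit_c = -vit_coeff / yield_boost, bio_c = 1), 0, 1000)
  bio_coef <- c(bio_c = -1)
  for (s in names(secrete)) {
    add_met(paste0(s, "_c"), "c"); add_met(paste0(s, "_e"), "e")
    bio_coef[paste0(s, "_c")] <- unname(secrete[s])
    add_rxn(paste0("T_", s),
            stats::setNames(c(-1, 1), paste0(s, c("_c", "_e"))), 0, 1000)
    add_rxn(paste0("EX_", s), stats::setNames(-1, paste0(s, "_e")), 0, 1000)
  }
  add_rxn("biomass", bio_coef, 0, 1000, biomass = TRUE)
  strain_model(id, do.call(rbind, mets), do.call(rbind, rxns), stoich)
}

## A potentiator: converts a trickle of `source` into the shared cofactor
## without growing itself (biomass bounds [0, 0]); it therefore donates to
## every cofactor user and receives nothing through cross-feeding.
potentiator_strain <- function(id, source, uptake_bound = 2, vit_yield = 2) {
  strain_model(
    id,
    data.frame(id = c(paste0(source, "_e"), paste0(source, "_c"),
                      "vit_c", "vit_e", "bio_c"),
               compartment = c("e", "c", "c", "e", "c")),
    data.frame(id = c(paste0("EX_", source), paste0("T_", source),
                      "VITSYN", "T_vit", "EX_vit", "biomass"),
               lb = c(-uptake_bound, 0, 0, 0, 0, 0),
               ub = c(0, 1000, 1000, 1000, 1000, 0),
               exchange = NA,
               biomass = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)),
    stats::setNames(
      list(stats::setNames(-1, paste0(source, "_e")),
           stats::setNames(c(-1, 1), paste0(source, c("_e", "_c"))),
           stats::setNames(c(-1, vit_yield), c(paste0(source, "_c"), "vit_c")),
           c(vit_c = -1, vit_e = 1),
           c(vit_e = -1),
           c(bio_c = -1)),
      c(paste0("EX_", source), paste0("T_", source),
        "VITSYN", "T_vit", "EX_vit", "biomass")))
}

#' Generate a deterministic degrader/helper/potentiator consortium
#'
#' Builds, from a \code{\link{dhp_spec}}, a toy consortium mirroring the
#' DHP-Com role structure: a degrader that is the sole consumer of the
#' primary carbon source and secretes a partially degraded intermediate;
#' helpers that either depend on that intermediate (obligate cross-feeders)
#' or catabolize the secondary carbon sources; and potentiators that
#' convert a bounded trickle of carbon into a cofactor required at trace
#' stoichiometry by the boosted growth routes of degrader and helpers,
#' while receiving no strain-derived metabolite themselves (unidirectional
#' donors). An optional bystander consumes the primary carbon at low yield
#' without interacting. All stoichiometries are fixed constants, so
#' generation is bit-reproducible.
#'
#' @param spec a \code{\link{dhp_spec}}.
#' @return list with \code{models} (named list of strain models),
#'   \code{media} (the C = 1..length(carbon_sources) media series),
#'   \code{roles} (named character vector).
#' @export
make_paperlike_consortium <- function(spec = dhp_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  cs <- spec$carbon_sources
  vc <- spec$vit_coeff
  models <- list(); roles <- character()
  models$DEG <- dual_route_strain("DEG", stats::setNames(1000, cs[[1]]),
                                  yield_basic = 0.5, yield_boost = 1,
                                  vit_coeff = vc, secrete = c(inter = 1))
  roles["DEG"] <- "degrader"
  helper_specs <- list(
    list(sources = c(inter = 1000), basic = 0.4, boost = 0.8, aux = TRUE),
    list(sources = stats::setNames(1000, cs[[min(2, length(cs))]]),
         basic = 0.5, boost = 1, aux = FALSE),
    list(sources = if (length(cs) >= 3)
           stats::setNames(rep(1000, length(cs) - 2L), cs[3:length(cs)])
         else numeric(),
         basic = 0.5, boost = 1, aux = FALSE))
  for (i in seq_len(spec$n_helpers)) {
    hs <- helper_specs[[i]]
    if (!length(hs$sources)) next
    id <- paste0("HLP", i)
    models[[id]] <- dual_route_strain(id, hs$sources, hs$basic, hs$boost,
                                      vit_coeff = vc, aux_source = hs$aux)
    roles[id] <- "helper"
  }
  pot_sources <- c(cs[[1]], cs[[min(length(cs), 2)]])
  for (i in seq_len(spec$n_potentiators)) {
    id <- paste0("POT", i)
    models[[id]] <- potentiator_strain(id, pot_sources[[i]])
    roles[id] <- "potentiator"
  }
  if (spec$bystander) {
    models$BYS <- make_toy_strain("BYS", stats::setNames(5, cs[[1]]),
                                  biomass_yield = 0.3)
    roles["BYS"] <- "bystander"
  }
  media <- build_media_series(paste0(cs, "_e"), spec$budget)
  list(models = models, media = media, roles = roles)
}

#' Generate a seeded random toy strain
#'
#' Draws a consumer with 1-2 uptakes from the given carbon pool, 0-2
#' secreted byproducts, random yields and uptake bounds. Used for
#' property-style tests; every draw passes \code{validate_strain_model}.
#'
#' @param seed integer seed.
#' @param id strain id.
#' @param carbons candidate carbon source ids.
#' @param byproducts candidate secreted metabolite ids.
#' @return a \code{\link{strain_model}}.
#' @export
random_toy_strain <- function(seed, id = paste0("R", seed),
                              carbons = c("c1", "c2", "c3"),
                              byproducts = c("x1", "x2")) {
  set.seed(seed)
  ups <- sample(carbons, sample(1:2, 1))
  bounds <- sample(c(1, 5, 10, 1000), length(ups), replace = TRUE)
  sec <- character()
  if (stats::runif(1) < 0.6)
    sec <- sample(setdiff(byproducts, ups), sample(1:2, 1))
  sec_y <- stats::setNames(round(stats::runif(length(sec), 0.2, 1), 2), sec)
  aux <- NULL
  rest <- setdiff(byproducts, c(ups, sec))
  if (length(rest) && stats::runif(1) < 0.3)
    aux <- stats::setNames(round(stats::runif(1, 0.05, 0.5), 2), rest[[1]])
  make_toy_strain(id, stats::setNames(bounds, ups), sec_y, aux,
                  biomass_yield = round(stats::runif(1, 0.3, 1), 2))
}

#' Generate a seeded random toy community with its medium
#'
#' Assembles 2-6 random toy strains (see \code{\link{random_toy_strain}})
#' on a random medium over the shared carbon pool. Deterministic given the
#' seed.
#'
#' @param seed integer seed.
#' @param n_strains number of member strains; drawn from 2..6 when NULL.
#' @return list with \code{models}, \code{medium},
#'   \code{community} (assembled \code{community_model}).
#' @export
random_toy_community <- function(seed, n_strains = NULL) {
  set.seed(seed)
  if (is.null(n_strains)) n_strains <- sample(2:6, 1)
  strains <- lapply(seq_len(n_strains), function(i)
    random_toy_strain(seed * 101L + i, id = paste0("S", i)))
  amts <- stats::setNames(round(stats::runif(3, 1, 20), 1),
                          c("c1_e", "c2_e", "c3_e"))
  med <- medium(amts, name = paste0("rand", seed))
  list(models = strains, medium = med,
       community = assemble_community(strains, med))
}

#' Write a toy model set to disk
#'
#' Emits one toy_json file per strain plus one TSV per medium, the on-disk
#' form consumed by the command-line interface.
#'
#' @param models named list of strain models.
#' @param media list of \code{medium} objects.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_toy_set <- function(models, media, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in models)
    write_strain_model(m, file.path(dir, paste0(m$strain_id, ".json")))
  for (med in media)
    write_medium_tsv(med, file.path(dir, paste0(med$name, ".tsv")))
  invisible(dir)
}
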