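#' Enumerate strain combinations
#'
#' All subsets of the strain pool with sizes in \code{[min_size, max_size]},
#' in deterministic order: by size, then lexicographically over the sorted
#' pool. A pool of 6 with sizes 2..6 yields the 57 interspecies
#' combinations of a six-member consortium screen.
#'
#' @param pool strain ids (character vector), or a single integer n for a
#'   pool \code{S1..Sn}.
#' @param min_size,max_size subset size range; \code{1 <= min_size <=
#'   max_size <= |pool|}.
#' @return list of character vectors (sorted strain ids).
#' @export
enumerate_combinations <- function(pool, min_size, max_size) {
  if (is.numeric(pool) && length(pool) == 1L)
    pool <- paste0("S", seq_len(pool))
  pool <- sort(unique(as.character(pool)))
  n <- length(pool)
  if (!(min_size >= 1 && min_size <= max_size && max_size <= n))
    stop("invalid size bounds: need 1 <= min_size <= max_size <= ", n)
  out <- list()
  for (k in min_size:max_size) {
    cmb <- utils::combn(pool, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Build the C = 1, 2, ... media series
#'
#' For each prefix length C of \code{carbon_sources}, a medium granting
#' \code{total_carbon_budget / C} to each of the first C sources -- the
#' single- versus multi-carbon series used to mimic single-pollutant and
#' co-contamination conditions (e.g. 100 glucose; 50 glucose + 50 citrate;
#' 25 each of glucose, citrate, acetate, fumarate). Every medium also
#' carries the essential nitrogen source at \code{nitrogen_amount} and
#' grants unlisted C/N-free inorganics the medium default of 1000.
#'
#' @param carbon_sources ordered carbon source metabolite ids.
#' @param total_carbon_budget total carbon amount split across sources
#'   (mmol/gDW); default 100.
#' @param nitrogen_id id of the nitrogen source (default \code{"nh4_e"}).
#' @param nitrogen_amount its amount (default 100 mmol/gDW).
#' @return list of \code{\link{medium}} objects named \code{C1, C2, ...}.
#' @export
build_media_series <- function(carbon_sources, total_carbon_budget = 100,
                               nitrogen_id = "nh4_e", nitrogen_amount = 100) {
  if (!length(carbon_sources)) stop("carbon_sources must be non-empty")
  if (total_carbon_budget <= 0) stop("total_carbon_budget must be > 0")
  lapply(seq_along(carbon_sources), function(C) {
    amts <- stats::setNames(rep(total_carbon_budget / C, C),
                            carbon_sources[seq_len(C)])
    amts[nitrogen_id] <- nitrogen_amount
    medium(amts, name = paste0("C", C))
  })
}

#' Configure a combination screen
#'
#' @param strain_pool strain ids to screen.
#' @param min_size,max_size combination size range.
#' @param media list of \code{\link{medium}} objects.
#' @param scenarios list of \code{\link{objective_spec}} objects.
#' @param growth_time also run the depletion simulation per combination to
#'   report growth times.
#' @param seed integer seed recorded with the screen.
#' @return object of class \code{screen_config}.
#' @export
screen_config <- function(strain_pool, min_size = 1,
                          max_size = length(strain_pool),
                          media, scenarios = list(objective_spec("no_limitation")),
                          growth_time = FALSE, seed = 1L) {
  if (!length(scenarios)) stop("at least one scenario is required")
  if (!length(media)) stop("at least one medium is required")
  if (!(min_size >= 1 && min_size <= max_size &&
        max_size <= length(strain_pool)))
    stop("invalid size bounds for pool of ", length(strain_pool))
  structure(list(strain_pool = sort(strain_pool), min_size = min_size,
                 max_size = max_size, media = media, scenarios = scenarios,
                 growth_time = growth_time, seed = as.integer(seed)),
            class = "screen_config")
}

#' Screen all strain combinations across media and scenarios
#'
#' Solves every (combination x medium x scenario) cell with community pFBA
#' in deterministic order. Solver failures are recorded in the status
#' column, never raised, so screens always complete.
#'
#' @param config a \code{\link{screen_config}}.
#' @param models named list of \code{\link{strain_model}} objects covering
#'   the pool.
#' @return data.frame with columns members, medium, scenario, status,
#'   total_biomass, one \code{biomass_<strain>} column per pool strain, and
#'   growth_time when requested.
#' @export
run_screen <- function(config, models) {
  miss <- setdiff(config$strain_pool, names(models))
  if (length(miss)) stop("no model for pool strain: ", miss[1L])
  combos <- enumerate_combinations(config$strain_pool, config$min_size,
                                   config$max_size)
  rows <- list()
  for (combo in combos) {
    for (med in config$media) {
      com <- assemble_community(models[combo], med)
      for (sc in config$scenarios) {
        sc_use <- sc
        if (sc$scenario == "target_strain" && !sc$target %in% combo) next
        row <- data.frame(members = paste(combo, collapse = "+"),
                          medium = med$name, scenario = sc$scenario,
                          status = "error", total_biomass = NA_real_)
        for (k in config$strain_pool) row[[paste0("biomass_", k)]] <- NA_real_
        sol <- tryCatch(solve_community_pfba(com, sc_use), error = function(e) NULL)
        if (!is.null(sol)) {
          row$status <- sol$status
          if (sol$status == "optimal") {
            row$total_biomass <- sol$total_biomass
            for (k in combo) row[[paste0("biomass_", k)]] <-
              unname(sol$strain_biomass[k])
          }
        }
        if (config$growth_time) {
          row$growth_time <- tryCatch(
            simulate_depletion(com, sc_use)$growth_time,
            error = function(e) NA_real_)
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

#' Write screen results to TSV
#' @param results data.frame from \code{\link{run_screen}}.
#' @param path output file.
#' @export
write_screen_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default medium perturbations for the sensitivity analysis
#'
#' For each carbon source: scale its amount by +/-\code{frac}; for each
#' ordered pair of carbon sources: reallocate \code{frac} of the first's
#' amount to the second, preserving the total carbon budget.
#'
#' @param med base \code{\link{medium}}.
#' @param carbon_sources which listed metabolites count as carbon sources;
#'   default: all listed metabolites except the nitrogen source
#'   \code{"nh4_e"}.
#' @param frac perturbation fraction (default 0.2).
#' @return named list of perturbed \code{medium} objects.
#' @export
default_perturbations <- function(med, carbon_sources = NULL, frac = 0.2) {
  if (is.null(carbon_sources))
    carbon_sources <- setdiff(names(med$amounts), "nh4_e")
  out <- list()
  for (m in carbon_sources) {
    for (s in c(1 + frac, 1 - frac)) {
      p <- med
      p$amounts[m] <- med$amounts[m] * s
      p$name <- paste0(med$name, "_", m, if (s > 1) "_up" else "_down")
      out[[p$name]] <- p
    }
  }
  if (length(carbon_sources) > 1) {
    for (a in carbon_sources) for (b in setdiff(carbon_sources, a)) {
      p <- med
      shift <- med$amounts[a] * frac
      p$amounts[a] <- med$amounts[a] - shift
      p$amounts[b] <- med$amounts[b] + shift
      p$name <- paste0(med$name, "_", a, "_to_", b)
      out[[p$name]] <- p
    }
  }
  out
}

#' Sensitivity of community biomass to medium perturbations
#'
#' Re-solves one strain combination under each perturbed medium and
#' reports the relative biomass change |B' - B| / B against the base
#' medium, plus the maximum across perturbations. A baseline at or below
#' the flux tolerance is flagged undefined instead of dividing.
#'
#' @param models named list of strain models.
#' @param combination strain ids of the community to analyze.
#' @param base_medium the reference \code{\link{medium}}.
#' @param perturbations list of perturbed media; default
#'   \code{\link{default_perturbations}(base_medium)}.
#' @param objective scenario to solve (default no_limitation pFBA).
#' @return list with \code{table} (data.frame: perturbation,
#'   total_biomass, relative_change), \code{base_biomass},
#'   \code{max_relative_change}, \code{undefined_baseline}.
#' @export
sensitivity_analysis <- function(models, combination, base_medium,
                                 perturbations = NULL,
                                 objective = objective_spec("no_limitation")) {
  if (is.null(perturbations))
    perturbations <- default_perturbations(base_medium)
  if (any(vapply(perturbations, function(p) any(p$amounts < 0), logical(1))))
    stop("perturbed amounts must remain >= 0")
  base <- solve_community_pfba(assemble_community(models[combination],
                                                  base_medium), objective)
  b0 <- if (base$status == "optimal") base$total_biomass else 0
  undefined <- b0 <= EPS_FLUX
  rows <- lapply(names(perturbations), function(nm) {
    p <- perturbations[[nm]]
    sol <- solve_community_pfba(assemble_community(models[combination], p),
                                objective)
    bt <- if (sol$status == "optimal") sol$total_biomass else NA_real_
    data.frame(perturbation = nm, total_biomass = bt,
               relative_change = if (undefined) NA_real_ else abs(bt - b0) / b0)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, base_biomass = b0,
       max_relative_change = if (undefined) NA_real_ else
         max(tab$relative_change, na.rm = TRUE),
       undefined_baseline = undefined)
}

#' Potentiator Contribution Index
#'
#' Relative performance gain, in percent, of the full
#' degrader-helper-potentiator consortium over the degrader-helper
#' baseline: \code{(DHP - DH) / DH * 100}. Performance may be any overall
#' community measure (biomass, degradation rate); negative values indicate
#' a detrimental third member.
#'
#' @param performance_dhp performance of the D+H+P consortium.
#' @param performance_dh performance of the D+H consortium; must be > 0.
#' @return PCI in percent.
#' @export
compute_pci <- function(performance_dhp, performance_dh) {
  if (!is.finite(performance_dh) || performance_dh <= 0)
    stop("PCI undefined for non-positive baseline")
  (performance_dhp - performance_dh) / performance_dh * 100
}

## IUPAC 2021 standard atomic weights, 4 significant figures.
ATOMIC_WEIGHTS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06, Na = 22.99, K = 39.098,
                    Cl = 35.45, Ca = 40.078, Mg = 24.305, Fe = 55.845,
                    Zn = 65.38, Br = 79.904)

#' Carbon-equivalent of a compound mixture
#'
#' Total molar carbon delivered by a set of compounds at given
#' concentrations in a given culture volume, plus the glucose mass that
#' would deliver the same molar carbon -- the computation behind
#' equivalent-glucose supplementation controls.
#'
#' @param compounds data.frame with columns \code{formula} and
#'   \code{conc_mg_per_L}; every formula must contain carbon.
#' @param volume_L culture volume in liters; > 0.
#' @return list with \code{mol_C} (total mol carbon),
#'   \code{equivalent_glucose_mg} (glucose mass with the same mol C), and
#'   \code{per_compound} breakdown.
#' @export
carbon_equivalence <- function(compounds, volume_L) {
  stopifnot(is.data.frame(compounds),
            all(c("formula", "conc_mg_per_L") %in% names(compounds)))
  if (volume_L <= 0) stop("volume_L must be > 0")
  if (any(compounds$conc_mg_per_L < 0)) stop("concentrations must be >= 0")
  per <- vapply(seq_len(nrow(compounds)), function(i) {
    f <- compounds$formula[i]
    el <- parse_formula(f)
    if (!"C" %in% names(el)) stop("formula without carbon: ", f)
    unknown <- setdiff(names(el), names(ATOMIC_WEIGHTS))
    if (length(unknown)) stop("no atomic weight for element '", unknown[1L],
                              "' in formula ", f)
    mw <- sum(el * ATOMIC_WEIGHTS[names(el)])
    c_frac <- el[["C"]] * ATOMIC_WEIGHTS[["C"]] / mw
    compounds$conc_mg_per_L[i] * volume_L * c_frac / ATOMIC_WEIGHTS[["C"]] / 1000
  }, numeric(1))
  mol_c <- sum(per)
  glc_mw <- sum(c(C = 6, H = 12, O = 6) * ATOMIC_WEIGHTS[c("C", "H", "O")])
  list(mol_C = mol_c,
       equivalent_glucose_mg = mol_c / 6 * glc_mw * 1000,
       per_compound = data.frame(formula = compounds$formula, mol_C = per))
}
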