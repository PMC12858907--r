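#' Assemble strain models into a community model
#'
#' Joins K single-strain models through a shared extracellular pool. Every
#' strain compartment is namespaced (\code{strain:reaction},
#' \code{strain:metabolite}); extracellular metabolites with the same bare id
#' in different strains map onto one pool metabolite. Each strain's exchange
#' reaction is rewired to transfer its metabolite between the strain and the
#' pool (flux > 0 = secretion into the pool), and the pool itself gains one
#' import reaction per metabolite, bounded above by the medium amount, and
#' one unbounded export reaction. At steady state every pool metabolite m
#' then satisfies sum_k v_ex_m^k + IP_m - EP_m = 0.
#'
#' @param strains list of \code{\link{strain_model}} objects with unique ids.
#' @param med a \code{\link{medium}} defining the import bounds.
#' @return object of class \code{community_model}.
#' @export
assemble_community <- function(strains, med) {
  if (!length(strains)) stop("need at least one strain")
  ids <- vapply(strains, function(s) s$strain_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate strain_id: ", ids[duplicated(ids)][1L])
  for (s in strains)
    if (!any(s$reactions$exchange))
      stop("strain '", s$strain_id, "' has no exchange reactions; it cannot ",
           "interact with the community")
  names(strains) <- ids

  met_rows <- list(); rxn_rows <- list(); trip <- list()
  pool <- character(); pool_formula <- character()
  ex_map <- list()
  for (s in strains) {
    k <- s$strain_id
    ns <- function(x) paste0(k, ":", x)
    exmet <- exchange_metabolites(s)
    met_rows[[k]] <- data.frame(id = ns(s$metabolites$id),
                                compartment = s$metabolites$compartment,
                                formula = s$metabolites$formula,
                                strain = k)
    rxn_rows[[k]] <- data.frame(id = ns(s$reactions$id),
                                lb = s$reactions$lb, ub = s$reactions$ub,
                                strain = k,
                                type = ifelse(s$reactions$exchange, "exchange",
                                              "internal"),
                                biomass = s$reactions$biomass)
    sm <- Matrix::summary(s$S)
    trip[[k]] <- data.frame(met = ns(rownames(s$S)[sm$i]),
                            rxn = ns(colnames(s$S)[sm$j]), coef = sm$x)
    for (r in names(exmet)) {
      m <- exmet[[r]]
      coef <- s$S[m, r]
      ## pool side mirrors the strain side: secretion (+flux removes met
      ## from the strain compartment) delivers it to the pool
      trip[[paste0(k, ":", r, ":pool")]] <-
        data.frame(met = m, rxn = ns(r), coef = -coef)
      if (!m %in% pool) {
        pool <- c(pool, m)
        pool_formula[m] <- s$metabolites$formula[match(m, s$metabolites$id)]
      } else if (is.na(pool_formula[m])) {
        pool_formula[m] <- s$metabolites$formula[match(m, s$metabolites$id)]
      }
      ex_map[[length(ex_map) + 1L]] <-
        data.frame(strain = k, reaction = ns(r), metabolite = m)
    }
  }
  pool_mets <- data.frame(id = pool, compartment = "pool",
                          formula = unname(pool_formula[pool]),
                          strain = NA_character_)
  import_bounds <- vapply(pool, function(m)
    medium_amount(med, m, pool_formula[[m]]), numeric(1))
  io_rxns <- rbind(
    data.frame(id = paste0("IP_", pool), lb = 0, ub = unname(import_bounds),
               strain = NA_character_, type = "import", biomass = FALSE),
    data.frame(id = paste0("EP_", pool), lb = 0, ub = Inf,
               strain = NA_character_, type = "export", biomass = FALSE))
  for (m in pool) {
    trip[[paste0("IP_", m)]] <- data.frame(met = m, rxn = paste0("IP_", m), coef = 1)
    trip[[paste0("EP_", m)]] <- data.frame(met = m, rxn = paste0("EP_", m), coef = -1)
  }

  mets <- rbind(do.call(rbind, met_rows), pool_mets)
  rxns <- rbind(do.call(rbind, rxn_rows), io_rxns)
  tr <- do.call(rbind, trip)
  S <- Matrix::sparseMatrix(i = match(tr$met, mets$id),
                            j = match(tr$rxn, rxns$id),
                            x = tr$coef,
                            dims = c(nrow(mets), nrow(rxns)),
                            dimnames = list(mets$id, rxns$id))
  structure(list(strains = strains, strain_ids = ids,
                 metabolites = mets, reactions = rxns, S = S,
                 pool_metabolites = pool,
                 pool_import_bounds = stats::setNames(unname(import_bounds), pool),
                 exchange_map = do.call(rbind, ex_map),
                 medium = med),
            class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat("Community model: ", length(x$strain_ids), " strains (",
      paste(x$strain_ids, collapse = ", "), "), ",
      length(x$pool_metabolites), " pool metabolites, medium '",
      x$medium$name, "'\n", sep = "")
  invisible(x)
}

#' Specify a community objective scenario
#'
#' Encodes the four community objectives used for max sum_k c^k v_biomass^k:
#' \describe{
#'   \item{no_limitation}{maximize the weighted sum of biomass fluxes; any
#'     strain's biomass may be zero.}
#'   \item{equal_abundance}{couple all strains to a common growth value
#'     (v_biomass^k = mu for every k) and maximize mu.}
#'   \item{defined_abundances}{couple v_biomass^k = a^k mu for given
#'     abundance fractions a^k and maximize mu.}
#'   \item{target_strain}{maximize the biomass of one target strain only,
#'     i.e. exclusive allocation of community resources to that strain.}
#' }
#'
#' @param scenario one of the four scenario names.
#' @param weights named non-negative weights c^k (no_limitation; default 1).
#' @param abundances named positive fractions a^k summing to 1
#'   (defined_abundances).
#' @param target strain id (target_strain).
#' @return object of class \code{objective_spec}.
#' @export
objective_spec <- function(scenario = c("no_limitation", "equal_abundance",
                                        "target_strain", "defined_abundances"),
                           weights = NULL, abundances = NULL, target = NULL) {
  scenario <- match.arg(scenario)
  if (scenario == "target_strain" && is.null(target))
    stop("target_strain scenario requires 'target'")
  if (scenario == "defined_abundances") {
    if (is.null(abundances)) stop("defined_abundances requires 'abundances'")
    if (any(abundances <= 0) || abs(sum(abundances) - 1) > 1e-8)
      stop("abundances must be positive and sum to 1")
  }
  if (!is.null(weights) && any(weights < 0)) stop("weights must be >= 0")
  structure(list(scenario = scenario, weights = weights,
                 abundances = abundances, target = target),
            class = "objective_spec")
}

## Bare LP ingredients of a community model: objective over reaction columns
## plus (for coupled scenarios) a trailing mu column and coupling rows.
community_lp <- function(model, objective) {
  K <- length(model$strain_ids)
  rx <- model$reactions
  n <- nrow(rx)
  bio_cols <- stats::setNames(match(rx$id[rx$biomass], rx$id),
                              rx$strain[rx$biomass])
  bio_cols <- bio_cols[model$strain_ids]
  A <- model$S
  b <- rep(0, nrow(A))
  lb <- rx$lb; ub <- rx$ub
  obj <- numeric(n)
  coupled <- objective$scenario %in% c("equal_abundance", "defined_abundances")
  if (objective$scenario == "no_limitation") {
    w <- rep(1, K); names(w) <- model$strain_ids
    if (!is.null(objective$weights)) w[names(objective$weights)] <- objective$weights
    obj[bio_cols] <- w[names(bio_cols)]
  } else if (objective$scenario == "target_strain") {
    if (!objective$target %in% model$strain_ids)
      stop("unknown target strain: ", objective$target)
    obj[bio_cols[objective$target]] <- 1
  } else {
    ## equal_abundance couples every strain to the same growth value mu;
    ## defined_abundances scales mu by the abundance fraction a^k
    a <- if (objective$scenario == "equal_abundance")
      stats::setNames(rep(1, K), model$strain_ids)
    else {
      miss <- setdiff(model$strain_ids, names(objective$abundances))
      if (length(miss)) stop("abundances missing for strain: ", miss[1L])
      objective$abundances[model$strain_ids]
    }
    ## add mu column and rows v_bio^k - a^k mu = 0
    A <- rbind(cbind(A, Matrix::Matrix(0, nrow(A), 1)),
               Matrix::sparseMatrix(i = rep(seq_len(K), 2L),
                                    j = c(unname(bio_cols), rep(n + 1L, K)),
                                    x = c(rep(1, K), -unname(a)),
                                    dims = c(K, n + 1L)))
    b <- c(b, rep(0, K))
    lb <- c(lb, 0); ub <- c(ub, Inf)
    obj <- c(obj, 0); obj[n + 1L] <- 1
  }
  list(obj = obj, A = A, b = b, lb = lb, ub = ub, n_rxn = n,
       bio_cols = bio_cols, coupled = coupled)
}

## Package an LP point into a community_solution.
community_solution <- function(model, objective, x, objective_value, status) {
  rx <- model$reactions
  fluxes <- if (is.null(x)) NULL else stats::setNames(x[seq_len(nrow(rx))], rx$id)
  strain_biomass <- stats::setNames(rep(0, length(model$strain_ids)),
                                    model$strain_ids)
  pool_flows <- list()
  if (!is.null(fluxes)) {
    strain_biomass[] <- vapply(model$strain_ids, function(k)
      fluxes[[rx$id[rx$biomass & !is.na(rx$strain) & rx$strain == k]]], numeric(1))
    for (m in model$pool_metabolites) {
      per <- model$exchange_map[model$exchange_map$metabolite == m, ]
      pool_flows[[m]] <- list(
        IP = unname(fluxes[[paste0("IP_", m)]]),
        EP = unname(fluxes[[paste0("EP_", m)]]),
        per_strain = stats::setNames(unname(fluxes[per$reaction]), per$strain))
    }
    resid <- max(abs(as.vector(model$S %*% fluxes)), 0)
    if (resid > EPS_FLUX)
      stop("internal error: community mass balance residual ", signif(resid, 3))
  }
  structure(list(strain_biomass = strain_biomass,
                 total_biomass = sum(strain_biomass),
                 fluxes = fluxes, pool_flows = pool_flows,
                 objective_value = objective_value, status = status,
                 scenario = objective),
            class = "community_solution")
}

#' @export
print.community_solution <- function(x, ...) {
  cat("Community solution (", x$scenario$scenario, "): status ", x$status,
      ", objective ", format(x$objective_value),
      ", total biomass ", format(x$total_biomass), "\n", sep = "")
  print(x$strain_biomass)
  invisible(x)
}

#' Solve community flux balance analysis
#'
#' Maximizes the scenario objective of \code{objective} over the community
#' LP: per-strain steady state, reaction bounds, and the extracellular pool
#' balance sum_k v_ex_m^k + IP_m - EP_m = 0 with 0 <= IP_m <= medium amount.
#' For the coupled scenarios (equal or defined abundances) an auxiliary
#' growth variable mu is maximized under v_biomass^k = a^k mu; when that
#' coupling is infeasible the community simply cannot grow at the imposed
#' composition, and a zero-growth optimal solution is returned rather than
#' an error.
#'
#' @param model a \code{community_model}.
#' @param objective an \code{\link{objective_spec}}.
#' @return a \code{community_solution}: per-strain biomass, all fluxes,
#'   per-pool-metabolite flows (IP, EP, per-strain exchange), objective
#'   value, status and scenario.
#' @export
solve_community <- function(model, objective = objective_spec("no_limitation")) {
  lp <- community_lp(model, objective)
  res <- lp_solve(lp$obj, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE)
  if (res$status == "infeasible" && lp$coupled) {
    zero <- rep(0, lp$n_rxn)
    return(community_solution(model, objective, zero, 0, "optimal"))
  }
  if (res$status != "optimal")
    return(community_solution(model, objective, NULL, NA_real_, res$status))
  community_solution(model, objective, res$x, res$objective, "optimal")
}

#' Solve community FBA with parsimonious import (pFBA)
#'
#' Two-stage lexicographic solve: stage 1 fixes the scenario optimum
#' (within 1e-6 relative), stage 2 minimizes the total community nutrient
#' import sum_m IP_m among stage-1 optima. Set \code{classic = TRUE} to
#' minimize the total absolute flux over all reactions instead (classical
#' parsimonious FBA) for comparison.
#'
#' @inheritParams solve_community
#' @param classic minimize total |flux| instead of total import.
#' @return a \code{community_solution}; \code{objective_value} is the
#'   stage-1 scenario optimum.
#' @export
solve_community_pfba <- function(model,
                                 objective = objective_spec("no_limitation"),
                                 classic = FALSE) {
  stage1 <- solve_community(model, objective)
  if (stage1$status != "optimal") return(stage1)
  z <- stage1$objective_value
  lp <- community_lp(model, objective)
  n <- length(lp$obj)
  ## pin the scenario objective: obj'v - slack = z_lo, slack >= 0; the
  ## slack keeps stage 2 feasible under round-off while staying far inside
  ## the 1e-6 mass-balance reporting tolerance
  z_lo <- z - 1e-9 * max(1, abs(z))
  A2 <- rbind(cbind(lp$A, Matrix::Matrix(0, nrow(lp$A), 1)),
              Matrix::sparseMatrix(i = rep(1L, sum(lp$obj != 0) + 1L),
                                   j = c(which(lp$obj != 0), n + 1L),
                                   x = c(lp$obj[lp$obj != 0], -1),
                                   dims = c(1L, n + 1L)))
  b2 <- c(lp$b, z_lo)
  lb2 <- c(lp$lb, 0); ub2 <- c(lp$ub, Inf)
  rx <- model$reactions
  if (!classic) {
    obj2 <- numeric(n + 1L)
    obj2[which(rx$type == "import")] <- 1
    res <- lp_solve(obj2, A2, b2, lb2, ub2, maximize = FALSE)
  } else {
    ## split v = p - q, p,q >= 0, minimize sum(p + q) over strain reactions
    nr <- lp$n_rxn
    split <- which(seq_len(n + 1L) <= nr)
    ns <- length(split)
    A3 <- cbind(A2, Matrix::Matrix(0, nrow(A2), 2L * ns))
    ## rows v_j - p_j + q_j = 0
    A3 <- rbind(A3, Matrix::sparseMatrix(
      i = rep(seq_len(ns), 3L),
      j = c(split, n + 1L + seq_len(ns), n + 1L + ns + seq_len(ns)),
      x = c(rep(1, ns), rep(-1, ns), rep(1, ns)),
      dims = c(ns, n + 1L + 2L * ns)))
    b3 <- c(b2, rep(0, ns))
    lb3 <- c(lb2, rep(0, 2L * ns))
    ub3 <- c(ub2, rep(Inf, 2L * ns))
    obj3 <- c(numeric(n + 1L), rep(1, 2L * ns))
    res <- lp_solve(obj3, A3, b3, lb3, ub3, maximize = FALSE)
  }
  if (res$status != "optimal") return(stage1)   # degenerate; keep stage 1
  community_solution(model, objective, res$x[seq_len(lp$n_rxn)], z, "optimal")
}

#' Total community import of a solution
#' @param solution a \code{community_solution}.
#' @return sum over pool metabolites of IP_m.
#' @export
total_import <- function(solution) {
  if (is.null(solution$pool_flows) || !length(solution$pool_flows)) return(0)
  sum(vapply(solution$pool_flows, function(p) p$IP, numeric(1)))
}

#' Simulate community growth on a finite nutrient pool
#'
#' Iterative depletion scheme over time steps of length \code{dt}: at each
#' step the import bound of every pool metabolite is
#' \code{min(remaining/dt, vmax)}, the community is solved with pFBA, pools
#' are decremented by the realized net import and credited with secreted
#' (exported) metabolites, and per-strain biomass increments
#' \code{v_biomass * dt} accumulate. The simulation stops when the step's
#' total biomass increment falls below \code{epsilon} (reported as
#' \code{pool_exhausted} when every finite pool has been drained, otherwise
#' \code{no_growth}) or after \code{max_steps}. \code{growth_time} is the
#' number of growth steps times \code{dt}.
#'
#' @inheritParams solve_community
#' @param dt step duration (h); > 0.
#' @param vmax per-metabolite import rate cap (mmol/gDW/h); > 0.
#' @param max_steps maximum number of steps.
#' @param epsilon biomass increment below which growth has stopped.
#' @return object of class \code{depletion_result} with fields
#'   \code{trajectory} (data.frame), \code{cumulative_biomass},
#'   \code{growth_time}, \code{stopped_because}.
#' @export
simulate_depletion <- function(model,
                               objective = objective_spec("no_limitation"),
                               dt = 1, vmax = 10, max_steps = 100,
                               epsilon = EPS_FLUX) {
  if (dt <= 0) stop("dt must be > 0")
  if (vmax <= 0) stop("vmax must be > 0")
  pool <- model$pool_metabolites
  remaining <- model$pool_import_bounds
  finite0 <- is.finite(remaining) & remaining > 0
  cum <- stats::setNames(rep(0, length(model$strain_ids)), model$strain_ids)
  traj <- list()
  stopped <- "max_steps"
  steps_grown <- 0L
  for (step in seq_len(max_steps)) {
    cap <- pmin(remaining / dt, vmax)
    cap[!is.finite(cap)] <- vmax
    m2 <- model
    m2$reactions$ub[m2$reactions$type == "import"] <-
      unname(cap[sub("^IP_", "", m2$reactions$id[m2$reactions$type == "import"])])
    m2$pool_import_bounds <- cap
    sol <- solve_community_pfba(m2, objective)
    inc <- if (sol$status == "optimal") sol$strain_biomass * dt else cum * 0
    if (sum(inc) < epsilon) {
      stopped <- if (step > 1L && all(remaining[finite0] <= epsilon))
        "pool_exhausted" else "no_growth"
      break
    }
    ip <- vapply(pool, function(m) sol$pool_flows[[m]]$IP, numeric(1))
    ep <- vapply(pool, function(m) sol$pool_flows[[m]]$EP, numeric(1))
    remaining <- pmax(remaining - ip * dt + ep * dt, 0)
    cum <- cum + inc
    steps_grown <- steps_grown + 1L
    row <- data.frame(step = step, time = step * dt)
    for (k in model$strain_ids) row[[paste0("biomass_", k)]] <- inc[[k]]
    for (m in pool) row[[paste0("pool_", m)]] <- unname(remaining[[m]])
    traj[[step]] <- row
  }
  structure(list(trajectory = if (length(traj)) do.call(rbind, traj) else
                   data.frame(step = integer(), time = numeric()),
                 cumulative_biomass = cum,
                 growth_time = steps_grown * dt,
                 stopped_because = stopped),
            class = "depletion_result")
}

#' @export
print.depletion_result <- function(x, ...) {
  cat("Depletion simulation: ", nrow(x$trajectory), " growth steps, ",
      "growth_time ", x$growth_time, ", stopped: ", x$stopped_because, "\n",
      sep = "")
  print(x$cumulative_biomass)
  invisible(x)
}

#' Per-strain maximum biomass under exclusive resource allocation
#'
#' For each strain k the community is solved with the target_strain
#' objective (all community resources devoted to k), giving the
#' genetically/stoichiometrically attainable maximum biomass, and the
#' finite-pool depletion simulation under the same objective supplies the
#' corresponding growth time. Per-strain solver failures are recorded as NA
#' rows rather than aborting the profile.
#'
#' @inheritParams simulate_depletion
#' @return data.frame with columns strain_id, biomass, growth_time.
#' @export
max_target_biomass_profile <- function(model, dt = 1, vmax = 10,
                                       max_steps = 100) {
  rows <- lapply(model$strain_ids, function(k) {
    obj <- objective_spec("target_strain", target = k)
    bio <- tryCatch({
      sol <- solve_community_pfba(model, obj)
      if (sol$status == "optimal") unname(sol$strain_biomass[k]) else NA_real_
    }, error = function(e) NA_real_)
    gt <- tryCatch(
      simulate_depletion(model, obj, dt = dt, vmax = vmax,
                         max_steps = max_steps)$growth_time,
      error = function(e) NA_real_)
    data.frame(strain_id = k, biomass = bio, growth_time = gt)
  })
  do.call(rbind, rows)
}

#' Write a community solution to JSON
#'
#' @param solution a \code{community_solution}.
#' @param path output file.
#' @export
write_solution_json <- function(solution, path) {
  out <- list(scenario = solution$scenario$scenario,
              status = solution$status,
              objective_value = solution$objective_value,
              total_biomass = solution$total_biomass,
              strain_biomass = as.list(solution$strain_biomass),
              pool_flows = lapply(solution$pool_flows, function(p)
                list(IP = p$IP, EP = p$EP, per_strain = as.list(p$per_strain))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
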