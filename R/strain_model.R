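## Flux threshold below which a value is treated as zero throughout the
## package, and the bound used when an exchange is "fully open".
EPS_FLUX <- 1e-6
OPEN_BOUND <- 1000

#' Construct a single-strain metabolic model
#'
#' A strain model holds the stoichiometric network of one organism: a
#' metabolite table, a reaction table with flux bounds, and the sparse
#' stoichiometric matrix S (metabolites x reactions). Steady-state flux
#' balance analysis on the model solves max c'v subject to S v = 0 and
#' LB <= v <= UB.
#'
#' Exchange reactions (boundary reactions touching exactly one extracellular
#' metabolite) and the single biomass reaction may be flagged explicitly; if
#' a flag column is absent it is detected structurally: a reaction with
#' exactly one metabolite, in compartment \code{"e"}, is an exchange, and a
#' reaction whose id contains \code{"biomass"} (case-insensitive) is the
#' biomass reaction. Ambiguous or missing biomass detection is an error.
#'
#' @param strain_id single non-empty string.
#' @param metabolites data.frame with columns \code{id}, \code{compartment}
#'   and optionally \code{name}, \code{formula}, \code{charge}.
#' @param reactions data.frame with columns \code{id}, \code{lb}, \code{ub}
#'   and optionally logical \code{exchange} and \code{biomass}.
#' @param stoichiometry named list: reaction id -> named numeric vector of
#'   metabolite coefficients (negative = consumed).
#' @return object of class \code{strain_model}.
#' @export
strain_model <- function(strain_id, metabolites, reactions, stoichiometry) {
  if (!is.character(strain_id) || length(strain_id) != 1L || !nzchar(strain_id))
    stop("strain_id must be a single non-empty string")
  mets <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  rxns <- as.data.frame(reactions, stringsAsFactors = FALSE)
  for (col in c("name", "formula")) if (is.null(mets[[col]])) mets[[col]] <- NA_character_
  if (is.null(mets$charge)) mets$charge <- NA_integer_
  if (anyNA(mets$id) || any(!nzchar(mets$id))) stop("metabolite ids must be non-empty")
  if (anyDuplicated(mets$id)) stop("duplicate metabolite id: ",
                                   mets$id[duplicated(mets$id)][1L])
  if (anyDuplicated(rxns$id)) stop("duplicate reaction id: ",
                                   rxns$id[duplicated(rxns$id)][1L])
  if (any(rxns$lb > rxns$ub))
    stop("reaction with lower bound above upper bound: ",
         rxns$id[rxns$lb > rxns$ub][1L])

  miss <- setdiff(names(stoichiometry), rxns$id)
  if (length(miss)) stop("stoichiometry given for undeclared reaction: ", miss[1L])
  S <- Matrix::Matrix(0, nrow(mets), nrow(rxns), sparse = TRUE,
                      dimnames = list(mets$id, rxns$id))
  for (rid in names(stoichiometry)) {
    coef <- stoichiometry[[rid]]
    unknown <- setdiff(names(coef), mets$id)
    if (length(unknown))
      stop("reaction '", rid, "' references undeclared metabolite: ", unknown[1L])
    S[names(coef), rid] <- as.numeric(coef)
  }

  ## structural exchange detection / verification
  n_mets_per_rxn <- Matrix::colSums(S != 0)
  e_mets <- mets$id[mets$compartment == "e"]
  only_e <- vapply(rxns$id, function(r) {
    touched <- rownames(S)[S[, r] != 0]
    length(touched) == 1L && touched %in% e_mets
  }, logical(1))
  if (is.null(rxns$exchange) || all(is.na(rxns$exchange))) {
    rxns$exchange <- unname(only_e & n_mets_per_rxn == 1L)
  } else {
    rxns$exchange <- as.logical(rxns$exchange)
    na <- is.na(rxns$exchange)
    rxns$exchange[na] <- unname(only_e & n_mets_per_rxn == 1L)[na]
    bad <- rxns$exchange & !only_e
    if (any(bad))
      stop("reaction '", rxns$id[bad][1L],
           "' flagged exchange but does not touch exactly one extracellular metabolite")
  }

  if (is.null(rxns$biomass) || all(is.na(rxns$biomass))) {
    cand <- grepl("biomass", rxns$id, ignore.case = TRUE)
    if (sum(cand) != 1L)
      stop("biomass reaction detection ambiguous for strain '", strain_id,
           "': ", sum(cand), " candidates; flag one explicitly")
    rxns$biomass <- cand
  } else {
    rxns$biomass <- as.logical(rxns$biomass)
    rxns$biomass[is.na(rxns$biomass)] <- FALSE
  }
  if (sum(rxns$biomass) != 1L)
    stop("strain '", strain_id, "' must have exactly one biomass reaction, found ",
         sum(rxns$biomass))

  structure(list(strain_id = strain_id,
                 metabolites = mets[, c("id", "name", "compartment", "formula", "charge")],
                 reactions = rxns[, c("id", "lb", "ub", "exchange", "biomass")],
                 S = S),
            class = "strain_model")
}

#' @export
print.strain_model <- function(x, ...) {
  cat("Strain model '", x$strain_id, "': ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions (", sum(x$reactions$exchange),
      " exchange), biomass = ", biomass_reaction(x), "\n", sep = "")
  invisible(x)
}

#' Id of the biomass reaction of a strain model
#' @param model a \code{strain_model}.
#' @return reaction id string.
#' @export
biomass_reaction <- function(model) {
  model$reactions$id[model$reactions$biomass]
}

## The single extracellular metabolite touched by each exchange reaction,
## as a named character vector (exchange reaction id -> metabolite id).
exchange_metabolites <- function(model) {
  ex <- model$reactions$id[model$reactions$exchange]
  out <- vapply(ex, function(r) rownames(model$S)[model$S[, r] != 0][1L], character(1))
  names(out) <- ex
  out
}

#' Define a growth medium
#'
#' A medium maps extracellular metabolite ids to the amount available to the
#' community (mmol/gDW). Metabolites not listed fall back on an elemental
#' rule: compounds whose formula contains neither carbon nor nitrogen
#' (water, phosphate, trace minerals ...) are treated as non-limiting and
#' receive \code{default_inorganic_amount}; organic (C- or N-containing)
#' compounds, and compounds without a formula, receive 0 so that nothing is
#' silently fed to the model.
#'
#' @param amounts named numeric vector, metabolite id -> amount (>= 0).
#' @param name medium label used in reports.
#' @param default_inorganic_amount amount granted to unlisted C/N-free
#'   compounds (default 1000 mmol/gDW).
#' @return object of class \code{medium}.
#' @export
medium <- function(amounts = numeric(), name = "medium",
                   default_inorganic_amount = 1000) {
  amounts <- unlist(amounts)
  if (length(amounts) && (is.null(names(amounts)) || any(!nzchar(names(amounts)))))
    stop("medium amounts must be named by metabolite id")
  if (any(amounts < 0)) stop("medium amounts must be >= 0")
  structure(list(name = name, amounts = amounts,
                 default_inorganic_amount = default_inorganic_amount),
            class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat("Medium '", x$name, "': ", length(x$amounts), " listed metabolites",
      " (default inorganic amount ", x$default_inorganic_amount, ")\n", sep = "")
  if (length(x$amounts)) print(x$amounts)
  invisible(x)
}

## Amount available for one metabolite under the medium's rules.
## formula may be NA (treated as organic, amount 0 unless listed).
medium_amount <- function(med, met_id, formula = NA_character_) {
  if (met_id %in% names(med$amounts)) return(unname(med$amounts[[met_id]]))
  if (is.na(formula)) return(0)
  el <- parse_formula(formula)
  if (!("C" %in% names(el)) && !("N" %in% names(el)))
    return(med$default_inorganic_amount)
  0
}

#' Parse an elemental formula
#'
#' Accepts plain Hill-style formulas such as \code{"C6H12O6"}; parenthesised
#' groups are not supported (genome-scale model formulas are flat).
#'
#' @param formula formula string.
#' @return named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) stop("empty formula")
  rest <- formula
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(gsub("\\s", "", formula)))
    stop("cannot parse formula '", formula, "'")
  el <- sub("[0-9]*$", "", toks)
  cnt <- as.numeric(ifelse(grepl("[0-9]+$", toks),
                           sub("^[A-Za-z]+", "", toks), "1"))
  tapply(cnt, el, sum)[unique(el)]
}

## Exchange lower bounds implied by a medium: uptake of metabolite m is
## limited to min(model capacity, medium amount); secretion bounds are not
## touched. Returns the model with modified reaction bounds.
apply_medium <- function(model, med, warn_unmatched = FALSE) {
  exmet <- exchange_metabolites(model)
  if (warn_unmatched) {
    un <- setdiff(names(med$amounts), exmet)
    if (length(un))
      message("medium entries without matching exchange metabolite ignored: ",
              paste(un, collapse = ", "))
  }
  for (r in names(exmet)) {
    m <- exmet[[r]]
    f <- model$metabolites$formula[match(m, model$metabolites$id)]
    amt <- medium_amount(med, m, f)
    i <- match(r, model$reactions$id)
    model$reactions$lb[i] <- max(model$reactions$lb[i], -amt)
    if (model$reactions$lb[i] > model$reactions$ub[i])
      model$reactions$ub[i] <- model$reactions$lb[i]
  }
  model
}

#' Solve flux balance analysis for one strain
#'
#' Maximizes the flux of \code{objective_reaction} (the biomass reaction by
#' default) subject to steady state \code{S v = 0} and reaction bounds, with
#' exchange uptake limited by the medium: the uptake (lower) bound of the
#' exchange reaction of metabolite m becomes \code{max(LB, -amount(m))};
#' secretion bounds are left as declared by the model. Exchange flux is
#' positive for secretion and negative for uptake.
#'
#' @param model a \code{strain_model}.
#' @param med a \code{medium}.
#' @param objective_reaction reaction id to maximize; default biomass.
#' @param warn_unmatched message about medium entries the model cannot see.
#' @return object of class \code{flux_solution}: list with \code{fluxes}
#'   (named vector), \code{objective_value}, \code{status}.
#' @export
solve_fba <- function(model, med, objective_reaction = NULL,
                      warn_unmatched = FALSE) {
  if (is.null(objective_reaction)) objective_reaction <- biomass_reaction(model)
  if (!objective_reaction %in% model$reactions$id)
    stop("unknown objective reaction: ", objective_reaction)
  bounded <- apply_medium(model, med, warn_unmatched)
  obj <- as.numeric(bounded$reactions$id == objective_reaction)
  res <- lp_solve(obj, bounded$S, rep(0, nrow(bounded$S)),
                  bounded$reactions$lb, bounded$reactions$ub, maximize = TRUE)
  fluxes <- NULL
  if (res$status == "optimal") {
    fluxes <- stats::setNames(res$x, bounded$reactions$id)
    resid <- max(abs(as.vector(bounded$S %*% res$x)), 0)
    if (resid > EPS_FLUX)
      stop("internal error: steady-state residual ", signif(resid, 3),
           " exceeds tolerance")
  }
  structure(list(fluxes = fluxes,
                 objective_value = if (res$status == "optimal") res$objective else NA_real_,
                 status = res$status),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("FBA solution: status ", x$status, ", objective ",
      format(x$objective_value), "\n", sep = "")
  invisible(x)
}

#' Quality-control checks for a strain model
#'
#' Runs the standard model curation checks: (a) growth under fully open
#' exchange bounds (FAIL when maximal biomass is at or below
#' \code{tolerance}), (b) a leak check with all exchange uptake closed
#' (FAIL when biomass can be produced from nothing), (c) elemental balance
#' of every internal reaction whose metabolites all carry formulas, and
#' (d) a list of reactions skipped for missing formulas.
#'
#' @param model a \code{strain_model}.
#' @param tolerance flux threshold for "zero biomass" (default 1e-6).
#' @return data.frame of class \code{qc_report} with columns \code{check},
#'   \code{target}, \code{status}, \code{detail}.
#' @export
validate_strain_model <- function(model, tolerance = EPS_FLUX) {
  rows <- list()
  ex <- model$reactions$exchange

  open <- model
  open$reactions$lb[ex] <- -OPEN_BOUND
  open$reactions$ub[ex] <- pmax(open$reactions$ub[ex], OPEN_BOUND)
  sol <- lp_solve(as.numeric(open$reactions$biomass), open$S,
                  rep(0, nrow(open$S)), open$reactions$lb, open$reactions$ub)
  growth <- if (sol$status == "optimal") sol$objective else 0
  rows[[length(rows) + 1L]] <- data.frame(
    check = "open_exchange_growth", target = model$strain_id,
    status = if (growth > tolerance) "PASS" else "FAIL",
    detail = paste0("max biomass ", signif(growth, 6)))

  closed <- model
  closed$reactions$lb[ex] <- pmax(closed$reactions$lb[ex], 0)
  closed$reactions$ub[ex] <- pmax(closed$reactions$ub[ex], 0)
  sol2 <- lp_solve(as.numeric(closed$reactions$biomass), closed$S,
                   rep(0, nrow(closed$S)), closed$reactions$lb, closed$reactions$ub)
  leak <- if (sol2$status == "optimal") sol2$objective else
    if (sol2$status == "unbounded") Inf else 0
  rows[[length(rows) + 1L]] <- data.frame(
    check = "closed_exchange_leak", target = model$strain_id,
    status = if (leak <= tolerance) "PASS" else "FAIL",
    detail = paste0("biomass with uptake closed ", signif(leak, 6)))

  fl <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  internal <- !model$reactions$exchange & !model$reactions$biomass
  skipped <- character()
  for (r in model$reactions$id[internal]) {
    mets <- rownames(model$S)[model$S[, r] != 0]
    if (anyNA(fl[mets]) || any(!nzchar(fl[mets]))) {
      skipped <- c(skipped, r)
      next
    }
    bal <- list()
    for (m in mets) {
      el <- parse_formula(fl[[m]])
      for (e in names(el))
        bal[[e]] <- (if (is.null(bal[[e]])) 0 else bal[[e]]) +
          model$S[m, r] * el[[e]]
    }
    imb <- names(bal)[vapply(bal, function(v) abs(v) > 1e-6, logical(1))]
    rows[[length(rows) + 1L]] <- data.frame(
      check = "elemental_balance", target = r,
      status = if (length(imb)) "FAIL" else "PASS",
      detail = if (length(imb))
        paste0("imbalanced in ", paste(imb, collapse = ",")) else "balanced")
  }
  if (length(skipped))
    rows[[length(rows) + 1L]] <- data.frame(
      check = "elemental_balance_skipped", target = paste(skipped, collapse = ","),
      status = "SKIP", detail = "missing formulas")
  rep <- do.call(rbind, rows)
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' Summarize a strain's metabolic traits
#'
#' Reports reaction, exchange-reaction and transport-reaction counts (a
#' proxy for the breadth of the strain's resource-utilization spectrum)
#' plus the FBA biomass objective on each supplied medium. Solver failures
#' for individual media are recorded as \code{NA} without aborting.
#'
#' @param model a \code{strain_model}.
#' @param media list of \code{medium} objects (possibly empty).
#' @return one-row data.frame: strain_id, n_reactions, n_exchange,
#'   n_transport, then one \code{biomass_<name>} column per medium.
#' @export
strain_trait_summary <- function(model, media = list()) {
  comp <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
  is_transport <- vapply(model$reactions$id, function(r) {
    cs <- unique(comp[rownames(model$S)[model$S[, r] != 0]])
    all(c("e", "c") %in% cs)
  }, logical(1))
  rec <- data.frame(strain_id = model$strain_id,
                    n_reactions = nrow(model$reactions),
                    n_exchange = sum(model$reactions$exchange),
                    n_transport = sum(is_transport))
  for (med in media) {
    sol <- solve_fba(model, med)
    rec[[paste0("biomass_", med$name)]] <-
      if (sol$status == "optimal") sol$objective_value else NA_real_
  }
  rec
}

#' Read a medium from a TSV file
#'
#' Expects columns \code{metabolite_id} and \code{amount_mmol_per_gDW};
#' lines starting with \code{#} are comments.
#'
#' @param path TSV file path.
#' @param name medium label; defaults to the file name.
#' @param default_inorganic_amount see \code{\link{medium}}.
#' @return a \code{medium}.
#' @export
read_medium_tsv <- function(path, name = NULL, default_inorganic_amount = 1000) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("metabolite_id", "amount_mmol_per_gDW") %in% names(df)))
    stop("medium TSV needs columns metabolite_id, amount_mmol_per_gDW: ", path)
  medium(stats::setNames(df$amount_mmol_per_gDW, df$metabolite_id),
         name = if (is.null(name)) sub("\\.tsv$", "", basename(path)) else name,
         default_inorganic_amount = default_inorganic_amount)
}

#' Write a medium to TSV
#' @param med a \code{medium}.
#' @param path output file.
#' @export
write_medium_tsv <- function(med, path) {
  df <- data.frame(metabolite_id = names(med$amounts),
                   amount_mmol_per_gDW = unname(med$amounts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a QC report to TSV
#' @param report a \code{qc_report} from \code{\link{validate_strain_model}}.
#' @param path output file.
#' @export
write_qc_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
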