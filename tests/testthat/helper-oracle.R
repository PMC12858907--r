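# Independent brute-force LP oracle.
#
# Enumerates every candidate vertex of {A x = b, lb <= x <= ub} by pinning
# each subset of n - rank(A) variables at a finite bound and solving the
# remaining equality system, then takes the best feasible candidate. For a
# pointed feasible region with a finite optimum, the optimum lies at such a
# vertex, so this enumeration is exact. Completely independent of the
# simplex implementation under test.
oracle_lp_max <- function(obj, A, b, lb, ub, tol = 1e-7) {
  A <- as.matrix(A)
  n <- ncol(A)
  r <- qr(A)$rank
  k <- n - r
  sets <- if (k == 0) list(integer(0)) else utils::combn(n, k, simplify = FALSE)
  best <- -Inf
  best_x <- NULL
  for (J in sets) {
    free <- setdiff(seq_len(n), J)
    grids <- lapply(J, function(j) {
      g <- numeric()
      if (is.finite(lb[j])) g <- c(g, lb[j])
      if (is.finite(ub[j]) && ub[j] > lb[j]) g <- c(g, ub[j])
      g
    })
    if (any(lengths(grids) == 0)) next
    AF <- A[, free, drop = FALSE]
    qAF <- qr(AF)
    if (qAF$rank < length(free)) next
    ## batch all bound assignments of this subset through one qr.coef call
    XJ <- if (length(J)) t(as.matrix(expand.grid(grids))) else
      matrix(0, 0, 1)
    RHS <- b - if (length(J)) A[, J, drop = FALSE] %*% XJ else
      matrix(0, length(b), 1)
    XF <- qr.coef(qAF, RHS)
    XF <- matrix(XF, ncol = ncol(RHS))
    resid_ok <- apply(abs(AF %*% XF - RHS), 2, max) <= tol
    for (ci in which(resid_ok & !colSums(is.na(XF)))) {
      x <- numeric(n)
      if (length(J)) x[J] <- XJ[, ci]
      x[free] <- XF[, ci]
      if (any(x < lb - tol) || any(x > ub + tol)) next
      val <- sum(obj * x)
      if (val > best) {
        best <- val
        best_x <- x
      }
    }
  }
  list(objective = best, x = best_x, feasible = is.finite(best))
}

# A seeded two-strain cross-feeding community small enough for exhaustive
# vertex enumeration (free dimension <= ~5): a producer eating one carbon
# source and secreting a byproduct, and a consumer growing on either the
# byproduct, a second carbon source, or both.
oracle_scale_community <- function(seed) {
  set.seed(seed)
  producer <- make_toy_strain("P1",
                              stats::setNames(sample(c(5, 10, 20), 1), "c1"),
                              secretions = c(x1 = round(stats::runif(1, 0.3, 1.5), 2)),
                              biomass_yield = round(stats::runif(1, 0.3, 1), 2))
  consumer_sources <- if (stats::runif(1) < 0.5) "x1" else c("x1", "c2")
  consumer <- make_toy_strain("P2",
                              stats::setNames(sample(c(5, 10), length(consumer_sources),
                                                     replace = TRUE),
                                              consumer_sources),
                              biomass_yield = round(stats::runif(1, 0.3, 1), 2))
  med <- medium(stats::setNames(round(stats::runif(2, 2, 15), 1),
                                c("c1_e", "c2_e")),
                name = paste0("oracle", seed))
  assemble_community(list(producer, consumer), med)
}

# Strain FBA oracle: builds the medium-bounded LP straight from the model
# tables (uptake bound = max(model LB, -amount)) and hands it to the
# enumeration above.
oracle_fba <- function(model, med) {
  rx <- model$reactions
  lb <- rx$lb
  ub <- rx$ub
  exmet <- commfba:::exchange_metabolites(model)
  for (r in names(exmet)) {
    m <- exmet[[r]]
    f <- model$metabolites$formula[match(m, model$metabolites$id)]
    amt <- commfba:::medium_amount(med, m, f)
    i <- match(r, rx$id)
    lb[i] <- max(lb[i], -amt)
    if (lb[i] > ub[i]) ub[i] <- lb[i]
  }
  oracle_lp_max(as.numeric(rx$biomass), model$S, rep(0, nrow(model$S)), lb, ub)
}

# Community oracle for the no_limitation scenario with unit weights.
oracle_community_total <- function(com) {
  rx <- com$reactions
  oracle_lp_max(as.numeric(rx$biomass), com$S, rep(0, nrow(com$S)),
                rx$lb, rx$ub)
}

# Minimum total import subject to total biomass >= z (pFBA stage-2 oracle):
# append the pinned-objective row with a bounded slack so the enumeration
# stays finite.
oracle_min_import <- function(com, z, slack_cap = 1e6) {
  rx <- com$reactions
  n <- nrow(rx)
  A <- rbind(cbind(as.matrix(com$S), 0),
             c(as.numeric(rx$biomass), -1))
  b <- c(rep(0, nrow(com$S)), z)
  lb <- c(rx$lb, 0)
  ub <- c(rx$ub, slack_cap)
  res <- oracle_lp_max(-c(as.numeric(rx$type == "import"), 0), A, b, lb, ub)
  list(objective = -res$objective, feasible = res$feasible)
}
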