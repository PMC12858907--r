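---
title: "Community flux balance analysis for consortium design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community flux balance analysis for consortium design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commfba)
```

## The model

`commfba` treats each strain $k$ of a community as a genome-scale (or toy)
stoichiometric network. A flux vector $v^k$ is feasible when it satisfies
steady state and the reaction bounds:

$$\sum_n S^k_{mn} v^k_n = 0 \quad \forall m \in M^k, \qquad
  LB^k_n \le v^k_n \le UB^k_n,$$

and single-strain flux balance analysis (FBA) maximizes the biomass flux
$v^k_{\mathrm{biomass}}$ subject to these constraints. Fluxes are in
mmol gDW$^{-1}$ h$^{-1}$; the biomass flux is the growth readout.

A community of $K$ strains is assembled by namespacing every strain
compartment and joining the strains through a shared extracellular pool.
Each strain's exchange reaction is rewired into a transfer reaction between
the strain and the pool, with flux $v[ex]^k_m > 0$ meaning secretion into
the pool. Every pool metabolite $m$ additionally gets an import reaction
$IP_m$ (bounded above by the medium) and an unbounded export $EP_m$, and at
steady state must satisfy

$$\Big(\sum_{k} v[ex]^k_m\Big) + IP_m - EP_m = 0 .$$

Because import and export are explicit reactions, this balance is a row of
the community stoichiometric matrix: any solution the solver returns
satisfies it to the reported residual (checked at $10^{-6}$ on every
solution the package constructs).

### Media

A medium maps extracellular metabolite ids to available amounts
(mmol/gDW). Amounts become the upper bounds of the pool import reactions
(for single-strain FBA, the uptake bounds of the exchange reactions, capped
by the model's own uptake capacity). Metabolites the medium does not list
fall back on an elemental rule: compounds whose formula contains neither C
nor N are treated as non-limiting inorganics and receive 1000 mmol/gDW;
C- or N-containing compounds, and compounds without a formula, receive 0 so
nothing is fed silently. `build_media_series()` constructs the
$C = 1, 2, \ldots$ series that splits a fixed carbon budget (default 100
mmol/gDW) evenly over a growing prefix of carbon sources, with the nitrogen
source fixed at 100 mmol/gDW — the single- versus multi-carbon ladder used
to mimic single-pollutant versus co-contamination conditions.

Interpreting amounts (totals per gDW) as flux bounds over a unit horizon is
the only encoding consistent with a single steady-state solve; the temporal
reading is delegated to the depletion simulation below.

### The four community objectives

`objective_spec()` encodes the four standard scenarios for the community
objective $\max \sum_k c^k v^k_{\mathrm{biomass}}$:

* **no_limitation** — maximize the (weighted) sum of biomass fluxes; any
  strain may end up at zero. This is the "maximum community biomass"
  objective used for combination screens.
* **equal_abundance** — add coupling constraints
  $v^k_{\mathrm{biomass}} = \mu$ for every $k$ and maximize the common
  growth $\mu$. We implement the scenario as a hard coupling rather than
  equal objective weights: equal weights are already covered by
  no_limitation, whereas the coupled reading answers a genuinely different
  question (what can every member achieve simultaneously?). A weighted
  no_limitation call recovers the soft reading if wanted.
* **defined_abundances** — couple $v^k_{\mathrm{biomass}} = a^k \mu$ for
  given abundance fractions $a^k$ and maximize $\mu$.
* **target_strain** — maximize one strain's biomass only: the "exclusive
  allocation of metabolic resources" question used for per-strain maximum
  biomass profiles.

When an abundance coupling is infeasible the community simply cannot grow
at that composition; the package returns an optimal solution with
$\mu = 0$ rather than raising, so screens over many compositions always
complete.

### Parsimonious solving

Community optima are usually degenerate. `solve_community_pfba()` runs a
two-stage lexicographic solve: stage 1 fixes the scenario optimum, stage 2
minimizes the total community nutrient import $\sum_m IP_m$ among stage-1
optima. Minimizing *import* (rather than the classical total absolute
flux) is the variant appropriate for community ecology here: it removes
gratuitous medium consumption and arbitrary alternate-optimum exchanges
before cross-feeding is read off a solution. The classical total-|flux|
variant remains available via `classic = TRUE` for comparison. The stage-1
objective is pinned with an absolute-scaled slack of $10^{-9}$ — far inside
the $10^{-6}$ reporting tolerance, so pinning never leaks visible biomass.

### Growth on a finite pool

`simulate_depletion()` supplies the temporal reading of a medium: at each
step of length `dt` the import bound of each pool metabolite is
`min(remaining/dt, vmax)`, the community is solved with pFBA, pools are
decremented by net import and credited with secretions, and biomass
increments `v_biomass * dt` accumulate. Secretions are credited back to the
pool *between* steps, which lets donated metabolites accumulate for
partners (time-lagged cross-feeding); crediting within the step is already
possible inside each single solve. The simulation stops when a step's
total biomass increment falls below $10^{-6}$ — reported as
`pool_exhausted` when every finite pool is drained, `no_growth`
otherwise — or at `max_steps`. `growth_time` is the number of growth steps
times `dt`. This scheme is a deliberate reconstruction: the upstream
literature reports growth times without defining the algorithm, so
absolute growth-time agreement with published values is not claimed,
only the qualitative ordering that richer media shorten or lengthen
growth depending on a strain's substrate range. It is not a full dynamic
FBA: biomass does not feed back into uptake capacity
($X(t)\cdot v$ kinetics are out of scope).

## Cross-feeding networks

`extract_cross_feeding()` turns an optimal solution into a directed
network: for every pool metabolite with at least one secreting strain
(flux $> \varepsilon$) and one consuming strain ($< -\varepsilon$,
$\varepsilon = 10^{-6}$), donor→recipient edges are created per metabolite.
With multiple donors or recipients, each recipient's uptake is allocated
proportionally to donor secretion magnitudes — the unique,
conservation-respecting, order-independent attribution — and medium import
counts as unattributed supply, never as a donor. Consequently, for every
metabolite the edge allocations plus unattributed import equal the total
uptake. Metabolite classes (amino acid, organic acid, carbohydrate,
vitamin, nucleotide, other) come from a user-overridable table; a metabolite
type is counted once per (donor, recipient, class) triple. A strain that
donates in at least one edge and receives in none is a *unidirectional
donor* — the network signature of a potentiator. Cross-feeding is always
read off the pFBA solution so near-zero LP noise and arbitrary alternate
optima do not create edges.

## The Potentiator Contribution Index

For a consortium with degrader (D), helper (H) and potentiator (P) roles,

$$\mathrm{PCI} = \frac{\mathrm{Perf}(DHP) - \mathrm{Perf}(DH)}
                      {\mathrm{Perf}(DH)} \times 100\%,$$

where performance is any overall community measure (here: community
biomass). `compute_pci()` requires a positive baseline and admits negative
values (a detrimental third member).

## The synthetic consortium generator

Real genome-scale models require genome-specific reconstruction and
curation, which is outside this package's scope. Instead,
`make_paperlike_consortium()` generates toy consortia whose *ecology* is
designed: a degrader that is the sole consumer of the primary carbon
source and obligately secretes a partially degraded intermediate; helpers
that either depend on that intermediate or catabolize secondary carbon
sources; potentiators that convert a small bounded trickle of carbon into
a cofactor required at trace stoichiometry (0.01 per unit carbon) by the
doubled-yield "boosted" growth routes of degrader and helpers; and an
optional low-yield bystander for the substitution control. Potentiators
are modeled as maintenance-only members (biomass bounds [0, 0]): they
donate without growing, which both matches the stable-abundance,
non-competing role and keeps "remove the degrader and nothing grows" true
by construction. Yield constants (0.5 basic vs 1.0 boosted for the
degrader, 0.4 vs 0.8 for the intermediate consumer) were chosen once to
keep every optimum hand-computable; on the default glucose medium the D+H
pair attains 70 and the D+H+P trio $180/1.01 \approx 178.2$, giving a PCI
near +155%, while the bystander substitution gives PCI = 0 exactly because
its yield is below the degrader chain's marginal yield.

Toy stoichiometries are deliberately *not* mass balanced (yields are
abstract), so elemental-balance QC is exercised on dedicated fixtures with
formulas instead. What passing tests on these fixtures demonstrate is the
correctness of the solver, the assembly, the screens and the network
extraction — not that any real six-strain community behaves this way;
absolute agreement with published biomass numbers would require the
original deposited strain models.

`random_toy_strain()` / `random_toy_community()` generate seeded random
consumers (1–2 substrates, 0–2 secreted byproducts, occasional
auxotrophies, ≤ 12 reactions) for property-style tests: conservation,
scenario ordering, superset monotonicity and oracle equivalence are
checked across batches of such communities under fixed seeds.

## Numerical choices

* **LP solver.** All solves run on the package's own bounded-variable
  two-phase primal simplex (`R/lp.R`): upper bounds are handled in the
  ratio test (bound flips), Dantzig pricing switches to Bland's rule under
  prolonged degeneracy, so termination is guaranteed and the pivot
  sequence — hence the returned vertex — is deterministic for identical
  inputs. A final refinement re-solves the optimal basis against the
  original system to remove accumulated pivot round-off. Feasibility
  tolerance is $10^{-9}$; all "is this flux zero" decisions use
  $\varepsilon = 10^{-6}$.
* **Verification.** The test suite checks the solver against an
  independent brute-force oracle that enumerates candidate vertices of
  the flux polytope (pinning each subset of $n - \mathrm{rank}(S)$
  variables at finite bounds and solving the remaining equality system).
  Fixture optima are frozen in `tests/testthat/ORACLE.tsv`, generated by
  that oracle and by closed-form hand solutions.
* **Degenerate inputs.** Infeasible models return status
  `"infeasible"` (never an exception); unbounded objectives return
  `"unbounded"`; empty media, zero baselines in sensitivity analyses and
  strains with no route from the medium all produce flagged results
  rather than errors.
* **Determinism.** Identical inputs produce byte-identical outputs:
  combination order is lexicographic over sorted strain ids, all tabular
  output is tab-separated UTF-8 with '.' decimals and fixed column order,
  and every CLI run writes a manifest (arguments, versions, seed, solver
  settings, output checksums).

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
fixtures: random communities of 2–6 strains with ≤ 12 reactions per
strain, the full 57-combination screen of the six-member demo consortium
over the $C = 1/2/4$ media series, and oracle comparisons on models whose
flux polytope has free dimension ≤ 5 (exhaustive vertex enumeration is
exponential, so oracle fixtures are kept small by design). These sizes
exercise every code path; nothing in the implementation is specific to
them, and the LP core has been cross-validated on substantially larger
random programs.

## Known limitations

* No thermodynamic or loopless constraints beyond the closed-exchange leak
  check; futile cycles that do not create mass are not detected.
* No spatial structure and no abundance-weighted dynamic FBA.
* SBML support covers the Level 3 fbc subset this package writes
  (compartments, species with formulas, stoichiometries, flux-bound
  parameters, one active objective); exotic SBML constructs (rules,
  events, annotations) are ignored.
* Cross-feeding attribution is a point estimate on the pFBA solution;
  edges whose existence varies across alternate optima are not flagged in
  the current release.
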