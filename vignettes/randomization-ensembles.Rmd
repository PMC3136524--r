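---
title: "Randomization ensembles for metabolic networks: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomization ensembles for metabolic networks: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metnull)
```

## The problem and the model

Global structural properties of metabolic networks — fat-tailed metabolite
degree distributions, high clustering, a bow-tie architecture — are often
presented as remarkable. Judging that requires a null model, and the usual
degree-preserving edge exchange is unusable for metabolism because rewired
"reactions" violate conservation of mass and atoms. The alternative
implemented here randomizes over *real* reactions: a genotype is a subset of
n reactions from a universe of N biochemically valid candidates, and nested
ensembles impose increasingly biological constraints:

* **R** — exactly n reactions;
* **RM** — additionally at most m_E distinct metabolites, where m_E is the
  reference organism's count (the cap, rather than equality, keeps the
  constraint set connected for sampling; the m = m_E slice is the subsample
  that attains the cap);
* **uRM** — reactions drawn only from the unblocked pool;
* **uRM-Vk** — flux-balance viability on the first k minimal environments.

Each ensemble is a finite set on which the target distribution is uniform.
`R` is sampled directly. The rest use a reaction-swap Metropolis chain:
remove a uniform member, add a uniform non-member, accept iff all
constraints hold. The proposal is symmetric (each ordered neighbor pair has
proposal probability 1/(n·(|pool|−n))), so accept-iff-valid is Metropolis
with a uniform target; the test suite verifies double stochasticity of the
transition matrix on an enumerable toy and chi-square uniformity of visit
frequencies on exhaustively enumerated constrained spaces.

**Ergodicity is assumed, not proven.** The swap chain is irreducible on the
size-n subsets themselves, but constraint sets could in principle split into
swap-disconnected components. This package follows the standard practice of
treating the chain as a random walk within the ensemble; `run_mcmc()` takes
seeds and arbitrary valid starts, so multi-seed/multi-start comparisons are
the supported diagnostic. A start that violates the ensemble is an error,
never silently repaired.

## Flux balance analysis core

Viability of a genotype is decided by linear programming over steady-state
fluxes: S v = 0 with bounds, maximizing the biomass flux Z. Conventions:

* irreversible reactions get [0, V], reversible [−V, V], with V = 1000 flux
  units; the carbon source may be taken up at 10, inorganics at 1000. Only
  the *sign* of Z_max matters for viability, so the magnitudes are
  conventional.
* exchange reactions are written as consumption of the external species
  (`glc_e ->`), so uptake is negative flux; secretion is allowed for every
  external metabolite in every environment, uptake only for medium members.
* viability threshold ε = 1e-6 absorbs LP round-off; the zero-flux tolerance
  in variability analysis is 1e-9.

A reaction is **blocked** iff its flux range is (0, 0) with all exchanges
open in both directions: the feasible set of any environment is a subset of
that polytope, so zero flux there implies zero flux everywhere. Detection
first solves a few probe FBAs with generic strictly positive objectives —
any reaction carrying flux in any LP optimum is unblocked and skipped — then
runs flux variability on the remainder, additionally clearing pending
reactions seen carrying flux in each optimum. The result is provably
identical to exhaustive variability analysis and order-independent.

A reaction is **necessary** iff deleting it from the full unblocked universe
drives Z_max to zero in at least one environment; the union over
environments is reported. A sound accelerator skips reactions with zero flux
in a wild-type optimum (that optimum remains feasible after their deletion).

Because no linear-programming package is available in the target
environment, the LPs are solved by an internal bounded-variable revised
simplex (dense basis inverse with product-form updates and periodic
refactorization, Dantzig pricing with a Bland fallback against cycling).
Every FBA polytope here contains v = 0, so the solver starts feasible from
the all-artificial basis and needs no phase 1. It is validated in the test
suite against `boot::simplex` on random flux polytopes and against
hand-solved chains. Degenerate alternate optima are irrelevant to every
consumer in the package: only optima values and zero/nonzero status are
used.

## Graph statistics

The bipartite graph links reactants → reaction → products, with both
orientations for reversible reactions. The metabolite-metabolite graph drops
a global currency list first, then draws an arc from every remaining
reactant to every remaining product per reaction (both directions if
reversible); self-loops are discarded and parallel arcs collapse. Isolated
non-currency metabolites stay as nodes — the construction defines nodes by
participation in reactions, not arc incidence — which deliberately lets
dead-end-laden genotypes dilute P_C and the bow-tie fractions.

Conventions that are genuinely open in the literature, and what this package
does:

* **Clustering.** "Fraction of triangles among connected triples" is
  ambiguous about the factor 3; the default is the transitivity convention
  C = 3·N_Δ/N₃ (the one standard graph libraries compute), with
  `normalization = "triangle_fraction"` exposing the unmultiplied variant.
* **Path statistics.** P_C and L are computed over *ordered* pairs of
  distinct nodes, with L averaged over reachable pairs only; a graph with no
  reachable pair reports L as missing, and degenerate graphs take C = 0,
  P_C = 0.
* **Bow tie.** Ties for the largest strong component break toward the
  component whose lexicographically smallest member sorts first, making
  results deterministic.
* The degree of a metabolite counts distinct reactions (a reversible
  reaction counts once), computed on the bipartite representation with
  currency metabolites included.

All statistics are cross-checked exactly against brute-force
adjacency-matrix oracles on random digraphs in the tests.

## Degree-tail fitting

The tail exponent γ maximizes the discrete power-law likelihood
−γ Σ ln kᵢ − n_tail · ln ζ(γ, k_min) over (1.01, 6) to 1e-6, with the
Hurwitz zeta evaluated by direct summation plus an Euler–Maclaurin tail
(relative error ≪ 1e-10). By default k_min is scanned over observed degrees
≥ 2, minimizing the Kolmogorov–Smirnov distance between empirical and
fitted tail CDFs, ties breaking toward the larger tail; a fixed-k_min mode
exists for reproduction attempts, since published exponents rarely state
their cutoff. `rpowerlaw()` samples the same family exactly (inverse CDF)
for calibration tests: the estimator recovers γ = 2.5 within ±0.05 at
n = 10⁴ and agrees with the closed-form approximation
γ̂ = 1 + n/Σ ln(kᵢ/(k_min−½)) within 0.02 for k_min ≥ 6.

## The synthetic world: what it emulates, what it does not

`generate_universe()` builds universes whose *statistical* structure mirrors
curated reaction databases, with planted ground truth that makes every
downstream claim checkable without an external download:

* **Currency couples** (default 6 pairs) attach to bulk reactions with
  probability 0.8, a second couple with conditional probability 0.2. This
  puts the reaction-degree mode at 4 with at most 3 non-currency
  participants, and gives currency species the high degrees that create the
  fat tail. (An alternative reading of the design notes — second couple with
  absolute probability p² = 0.64 — would make two couples the modal case and
  push the mode to 6, contradicting both the mode-4 regime and "sometimes
  two"; the conditional-0.2 reading is implemented.)
* **Core pool with preferential attachment.** Bulk reactions draw 1–3
  non-currency participants from an exchangeable core pool, reusing
  metabolites with weight (degree+1)^α. Defaults (pool ≈ 0.6 × reactions,
  new-metabolite probability 0.5) put random subsets in the sparse,
  fragmented regime of real unblocked reaction sets — this is what makes
  added constraints *increase* connectivity, the phenomenon the ensembles
  exist to exhibit. At 5000 reactions the metabolite degree tail fits with
  γ between 2 and 3, the empirically observed range.
* **Planted dead ends** (default 50 of 250, echoing the roughly half-blocked
  composition of merged reaction databases) touch fresh metabolites used
  nowhere else, so they are provably blocked with no LP needed — independent
  ground truth for `find_blocked()`.
* **A biomass backbone** runs from each environment's carbon source through
  committed (irreversible) entry steps into a reversible interconversion
  core producing all biomass precursors, with parallel routes for some
  precursors. Entry and single-route steps are the planted essential set;
  parallel-route reactions never are. Backbone steps secrete core-pool
  byproducts and some bulk reactions consume backbone intermediates,
  coupling the pathway into the bulk graph the way central metabolism
  couples into the rest — without these couplings a forced backbone would
  *dilute* connectivity instead of raising it, inverting the constraint
  trend. Reversible interconversions give viable networks the cycle-rich
  strongly connected core observed in real metabolism. Every non-dead-end
  reaction touches only producible metabolites when exchanges are open, so
  blocked recovery is exact by construction.
* Backbone-fed bulk reactions are irreversible: their reverse would
  fabricate a second producer of a backbone intermediate and silently break
  the planted-essentiality guarantee.

What the generator does **not** emulate: element and charge balance, real
stoichiometric coefficients, compartments beyond an external/internal
split, thermodynamics, and gene–protein–reaction structure. A green test on
synthetic universes therefore establishes the correctness of the
*machinery* (LP, detection screens, sampling, statistics) and the
qualitative constraint phenomenology — not any quantitative claim about a
real organism, which requires a real curated universe as input.

## Numerical and measurement choices

* Chain defaults follow the published protocol: 10⁵ burn-in swaps, then
  saving every 1000th genotype until 1000 are saved; rejected proposals
  advance the step counter, and the acceptance rate is computed over the
  sampling phase only. Identical seeds reproduce saved genotype sequences
  bit-for-bit.
* Viability results are cached per (genotype, environment), so rejected
  revisits are free; the cache can only return what `is_viable()` computes,
  and cached chains are compared against direct evaluation in tests.
* Uniformity diagnostics record visit frequencies every 50 attempted swaps
  rather than every step: consecutive Metropolis states differ by at most
  one swap, and raw per-step counts are so autocorrelated that a naive
  chi-square statistic is inflated for a perfectly correct sampler. The
  interval is a measurement choice fixed in advance of any test outcome.
* Ensemble summaries use the population standard deviation (n denominator),
  stated in output headers; z-scores of the reference within an ensemble are
  reported as missing when the SD is zero.
* Equation parsing nets a metabolite appearing on both sides and rejects a
  zero net; duplicate mentions on one side sum. Coefficients render as
  full-precision decimals so write→read round-trips are exact.
* The universe container tolerates the absence of a biomass reaction (pure
  graph work needs none); FBA entry points require exactly one and say so.

## Known limitations

* The simplex is dense; universes beyond a few thousand metabolites would
  need a sparse factorized implementation or an external solver.
* Necessity is defined by single deletions; synthetically lethal pairs are
  invisible to it (as they are to the definition it implements).
* The KS-based k_min scan can choose small cutoffs on strongly curved
  empirical tails; fixed-k_min mode is provided where comparability matters.
* MCMC ergodicity across strongly constrained viability sets is assumed (see
  above); the package surfaces diagnostics rather than pretending to a
  proof.
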