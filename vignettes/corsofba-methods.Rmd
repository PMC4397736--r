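---
title: "Protein-cost minimization in the sub-optimal flux space: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein-cost minimization in the sub-optimal flux space: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corsofba)
```

## The model

A constraint-based metabolic model is a stoichiometric matrix $S$ (rows =
metabolites, columns = reactions) with flux bounds $l \le v \le u$ and the
steady-state assumption $S v = 0$. Ordinary FBA maximizes one designated
objective flux (typically a biomass pseudo-reaction) over this polytope.
Two well-known problems follow: the optimum is usually degenerate in the
internal fluxes, and real cells often operate below their theoretical
maximum.

`corsofba` addresses both with a two-step program. First the objective
optimum $Z^\*$ is computed by FBA. Then, for a chosen fraction
$f \in (0, 1]$, the objective flux is **fixed** at $f \cdot Z^\*$ and the
total enzyme protein cost

$$\sum_i J_i \cdot MW_i \cdot \exp\!\left(0.02 \cdot \Delta_r G'^{\circ}_i\right)$$

is minimized, where $J_i \ge 0$ is the flux through one *direction* of
reaction $i$, $MW_i$ its enzyme molecular weight (kDa) and
$\Delta_r G'^{\circ}_i$ the standard Gibbs free energy of reaction
(kcal/mol). Sweeping $f$ traces how the cost-optimal flux distribution
reorganizes as the cell moves away from maximal growth — in particular the
overflow-metabolism transition from high-yield, enzymatically expensive
respiration-like routes to cheap low-yield fermentation-like routes.

### The cost term and its assumptions

* **Molecular weight** proxies the resource investment needed to express
  enough enzyme to carry a unit of flux. Only relative magnitudes matter to
  the LP; the package assumes the table is uniformly in kDa.
* **Thermodynamic penalty.** For reversible reactions each direction is
  weighted by $\exp(\pm 0.02\,\Delta_r G'^{\circ})$: the favorable
  direction gets a factor below one, the unfavorable one above one, and the
  two factors are exact reciprocals. Irreversible reactions carry factor 1.
  The scale 0.02 per kcal/mol keeps the exponential from dominating the
  molecular-weight term (an unscaled Boltzmann factor would effectively
  pre-decide directionality from thermodynamics alone). Because the scale
  is defined as $0.02\,RT$ mol/kcal, $RT$ cancels and the penalty is
  temperature-independent. It is exposed as `alpha_scaled` on
  [thermo_factor()] and [build_cost_coefficients()].
* **No turnover rates or affinities.** The cost deliberately omits
  $k_{cat}$ and substrate affinity; those parameters are scarce and highly
  condition-dependent. Consequently the method ranks pathways by expression
  cost, not by kinetics.
* **Zero-cost rule.** Reactions without an associated enzyme (exchanges,
  diffusion, spontaneous reactions, maintenance pseudo-reactions) cost
  exactly zero under every cost type. The cost table's `enzyme` flag
  overrides the model's gene association; reactions listed in neither are
  treated as non-enzymatic. Whether spontaneous gene-associated reactions
  should count as enzymatic is genuinely ambiguous; making the cost table
  authoritative keeps the decision in user-auditable data rather than in
  code.
* **Missing data.** Missing molecular weights are imputed with the median
  of the known enzyme weights (arithmetic mean of the two central values
  for even counts). A missing $\Delta_r G'^{\circ}$ means *no penalty*
  (factor 1), not penalty at $\Delta_r G'^{\circ} = 0$ — operationally the
  same number, but the interpretation is "no estimate available", and the
  imputation provenance is kept in the `mw_imputed` column.
* **One MW per reaction.** Isozymes are resolved upstream, in whatever
  pipeline prepares the cost table; the model stays single-valued.

### Implementation as a pure LP

Every enzyme-associated reaction that can run backwards is split into
irreversible parts `<id>__f` / `<id>__b` with negated stoichiometries. Each
enzyme-associated direction produces a cost pseudo-metabolite
(`protein_cost__x`, in its own pseudo-compartment so mass-balance tooling
ignores it) with coefficient equal to its per-unit cost; one sink reaction
(`COST_SINK`) is the only consumer. At steady state the sink flux therefore
*is* the total protein cost, and step two is "minimize one flux" — no
absolute values, no quadratic terms. Non-enzymatic reactions are left
unsplit: their cost is zero, so splitting them would only enlarge the LP
without changing any optimum.

Because both directions of a split pair carry positive cost, a futile
forward+backward cycle strictly increases the sink flux; cost-minimal
solutions run at most one direction of every pair, and the net fluxes
(forward − backward) satisfy the original steady state exactly.

## Numerical choices

* **Objective fixed by equality.** The fraction constraint is imposed by
  coincident bounds at $f \cdot Z^\*$. A `geq_objective` flag relaxes it to
  a lower bound; on sensible models cost minimization drives the objective
  to the bound anyway, so equality is the reproducible default.
* **LP solver.** All programs have the form $\min c^\top v$,
  $S v = 0$, $l \le v \le u$ with finite bounds. The package solves them
  with an internal bounded-variable revised simplex using Bland's
  anti-cycling rule for both entering and leaving choices. Steady-state
  LPs have an all-zero right-hand side and are therefore massively
  degenerate; Bland's rule makes termination provable and the pivot
  sequence deterministic given the column order. Phase 1 drives signed
  artificial variables to zero; phase 2 optimizes with artificials locked.
  Tolerance 1e-9; dense algebra (the intended problems have tens of
  columns). The test suite validates the solver against exhaustive vertex
  enumeration and against SciPy's HiGHS implementation on randomized
  networks.
* **Tie-breaking.** Alternate cost-minimal optima are resolved by a
  documented second lexicographic step: with the cost sink fixed at its
  minimum, the total flux through the split columns is minimized. This
  removes residual futile cycles and pins down a reproducible
  representative. Degeneracy among non-enzymatic reversible reactions can
  in principle remain; it does not affect cost, objective, or any reported
  summary.
* **Cleanup.** Fluxes below 1e-9 in magnitude are snapped to zero.
* **Bounds.** "Arbitrarily large" bounds are encoded as ±1000 (the common
  COBRA convention; configurable via `big_bound`). The cost-sink bound is
  derived from the cost coefficients and column bounds so it never
  truncates a feasible solution.
* **Default sweep grid** is 0.50–1.00 in steps of 0.01. The step is a
  reporting resolution, not a solver parameter.

## Fundamental pathways

Extreme-pathway analysis enumerates the generating rays of the flux cone
$\{v \ge 0 : S v = 0\}$ of the fully split network. On realistic models the
count explodes, largely because every currency-metabolite balancing loop
(ATP hydrolysis variants, proton transport cycles, ...) multiplies each
core route into many near-identical pathways.

The decomposition here removes a configurable set of currency metabolites
*by base name across all compartments* and enumerates extreme rays of the
reduced cone. Three structural considerations are enforced or surfaced:

1. a removed metabolite disappears from **every** reaction;
2. reactions emptied by the removal are dropped — and only those, so no
   retained reaction loses a partner that is still in the model;
3. retained reactions that become pure sources or sinks are *flagged* (a
   `warnings` table on the reduced model), not dropped: such implicit
   exchanges do not invalidate the decomposition but should be known.

Each fundamental pathway is annotated with its **imbalance**
$S_{\text{orig}} \cdot v$ — zero on every retained metabolite, generally
non-zero on the removed currency rows. The imbalance is what the balancing
loops would have to absorb; `recover_pathway()` demonstrates this
constructively by re-adding flux through the removed reactions to produce
an exactly balanced full-model vector.

### Exact arithmetic

Enumeration uses the double-description method with the classical
combinatorial adjacency test, inserting rows by increasing support size.
All arithmetic is exact: stoichiometric rows are first scaled to integers
(row scaling leaves the cone unchanged), every generated ray is reduced by
its GCD, and a guard trips if any intermediate magnitude approaches the
exact-integer range of doubles (2^40, far below the 2^53 limit). Rays whose
support is exactly one forward/backward pair (trivial two-cycles created by
splitting) are removed; proportional duplicates collapse by canonical
integer scaling. Enumeration refuses networks with more than `max_cols`
(default 80) split columns, since the algorithm is exponential in the worst
case; the guard is a usability decision, not a correctness one.

Internal cycles — rays with zero flux on every exchange reaction — are
flagged `is_internal_loop` (the thermodynamically infeasible "type III"
cycles) and excluded from energy classification.

### ATP potential, conversion costs, classification

Energy pathways are compared per mmol of glucose: each pathway is rescaled
so its glucose uptake is 1 (pathways without glucose uptake are reported
per pathway unit and flagged). The **ATP potential** is the ATP imbalance
plus, for every configured energy carrier (defaults: NADH, NADPH,
ubiquinol-8, FADH2), the carrier imbalance credited at the carrier's ATP
yield. The yield and its cost come from an LP on the full cost-augmented
model with all uptakes closed: inject one unit of reduced carrier (
regenerating its oxidized partner), maximize the ATP drain, then minimize
the protein cost at that yield.

Two decisions here were genuinely open and are package conventions:

* **Consumed carriers debit the potential symmetrically** (a pathway that
  burns NADH loses `yield × amount` of potential ATP). Crediting only
  positive imbalances would make carrier-consuming detours look free.
  Conversion *costs*, however, are added only for over-produced carriers —
  the consuming pathway uses the carrier directly rather than converting
  it.
* **NADPH is credited like the other carriers** by default. Whether a
  transhydrogenase-equivalent path exists determines its actual yield; if
  the model has none, the conversion LP returns yield 0 and the credit
  vanishes on its own, which is the behavior that degrades most gracefully.

The pathway's **total cost** is its own enzyme cost (per-direction cost
coefficients applied to its fluxes) plus the conversion costs of
over-produced carriers; **cost per ATP** is total cost over ATP potential
(infinite when the potential is non-positive). Classification runs Pareto
dominance on (maximize ATP potential, minimize cost per ATP): non-dominated
pathways are **OP** (optimal); dominated pathways that reach the frontier
when their coordinates are relaxed by a 10% margin (configurable) are
**NOP** (near-optimal); the rest are `other`.

## What the fixtures emulate — and what they do not

The fixtures are the package's study conditions, constructed rather than
downloaded:

* `make_glycolysis_fixture()` encodes textbook glycolysis from a PTS
  glucose uptake to D-lactate secretion (net +2 ATP, +2 lactate per
  glucose) together with a balancing set: ATP maintenance hydrolysis,
  reversible ATP synthase, a lactate/H+ symport and an inward proton leak.
  The full model admits several extreme pathways sharing the core route;
  currency removal collapses them to exactly one fundamental pathway with
  the +2 ATP / −2 ADP / −2 Pi / +2 H2O imbalance. One physical subtlety is
  deliberate: the proton transporter is an inward-only leak, because a
  free *outward* pump next to an ATP synthase is a perpetual-motion proton
  cycle that unbounds the ATP optimum — the same artifact type III loops
  produce in real reconstructions.
* `make_overflow_fixture()` is the minimal enzyme-cost/energy-yield
  tradeoff: two routes with yields 2 and 1 and per-flux costs 10 and 3
  (cost per biomass 5 vs 3), glucose bound 10. At $f = 1$ the high-yield
  route is forced by the glucose limit; below $f^\* = y_{lo}/y_{hi} = 0.5$
  the cheap route carries everything; between the two the routes mix
  linearly. Defaults were chosen once so that the switch sits strictly
  inside a 0.3–1.0 sweep and every quantity is hand-computable.
* `make_loop_fixture()` contains a three-reaction internal cycle next to a
  working chain; the seed permutes reaction order only, to exercise
  order-independence.
* `make_etc_fixture()` is a three-reaction electron-transport toy (4
  protons pumped per NADH, 2 protons per ATP, yield 2 ATP/NADH) for the
  carrier-conversion LP.
* `make_random_toy_model()` draws small two-route networks with
  seed-determined yields, reversibility, molecular weights and Gibbs
  energies, used for the oracle cross-checks.

What passing on these fixtures shows: the LP core, the cost accounting, the
enumeration and the annotations are correct on networks where every number
can be verified independently (exhaustive vertex enumeration, exhaustive
support-minimal ray search, SciPy HiGHS, and hand arithmetic). What it does
not show: behavior at genome scale. Real reconstructions bring thousands of
columns (the dense simplex would need sparse refactorization), blocked
reactions, non-integer biomass stoichiometries (the enumeration's
integerization would refuse pathological denominators), and currency lists
that genuinely matter — the defaults here are the common loop-formers, not
a validated list for any particular organism. The enumeration guard
(`max_cols = 80`) makes the intended scope explicit: pathway decomposition
is for reduced or central-carbon-scale networks.

Problem sizes used by the shipped test-and-acceptance runs: fixtures up to
27 augmented columns; ~22 randomized LP cross-checks on models of up to 9
augmented columns; ~22 randomized cone cross-checks on matrices of up to 8
columns (12 after splitting); sweeps at grid step 0.05–0.25. These sizes
were chosen so every oracle is exhaustive; the package itself handles
larger instances subject to the notes above.

## Known limitations

* Growth-rate prediction is out of scope: fixing $f$ explores flux
  reorganization, it does not map dilution rates to fractions.
* The cost model ignores enzyme kinetics ($k_{cat}$, affinities) and
  regulation; it ranks flux distributions by expression economy only.
* Degeneracy among zero-cost (non-enzymatic) reversible reactions is not
  fully resolved by the lexicographic step.
* The double-description enumeration is exponential; use the currency
  reduction aggressively, or restrict to the subsystem of interest.
* Pearson correlation against measured fluxes is undefined for
  zero-variance vectors and is reported as `NA` rather than silently
  dropped.
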