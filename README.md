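# corsofba

Constraint-based metabolic models predict growth well, but internal fluxes
poorly: the flux balance analysis (FBA) optimum is rarely unique, and cells
often do not grow at their theoretical maximum in the first place. `corsofba`
explores the **sub-optimal solution space** with a two-step optimization:

1. maximize the biomass (or any) objective by ordinary FBA, obtaining the
   optimum `Z*`;
2. fix the objective flux at a chosen fraction `f · Z*` (equality
   constraint) and **minimize an enzyme protein cost** over the remaining
   degrees of freedom.

The cost of running reaction *i* at flux `J_i` is

```
J_i · MW_i · exp(0.02 · ΔrG°'_i)        [ΔrG°' in kcal/mol, MW in kDa]
```

where `MW_i` is the molecular weight of the catalyzing enzyme and the
exponential is a thermodynamic penalty applied per direction of reversible
reactions (the favorable direction is discounted, the unfavorable one
surcharged; irreversible reactions carry factor 1). The exponent scale 0.02
per kcal/mol balances the two contributions so that neither molecular weight
nor thermodynamics dominates. Implementation-wise, every enzyme-associated
reversible reaction is split into irreversible forward/backward parts, each
direction produces a *cost pseudo-metabolite* at its per-unit cost, and a
single sink reaction drains that metabolite — so "total protein cost" is
just the sink flux, and cost minimization is an ordinary LP. Four cost types
are available: `combined` (MW × thermodynamic), `mw`, `thermo`, and
`uniform` (which reduces to a pFBA-style minimization of total enzymatic
flux).

The package also implements a **Fundamental Pathways** decomposition for
interpreting the energy metabolism: currency metabolites (ATP/ADP, NAD(H),
protons, water, phosphate, ...) are removed from the network, the extreme
rays of the reduced flux cone are enumerated exactly (integer
double-description algorithm), and each pathway is annotated with the
currency *imbalance* it would cause in the original model, its ATP
production potential (crediting energy carriers such as NADH at their
cheapest conversion yield), its protein cost per ATP, and an
optimal/near-optimal (OP/NOP) Pareto classification — the analysis that
explains overflow metabolism as a tradeoff between energy yield per glucose
and enzyme cost per ATP.

It is aimed at systems-biology users of COBRA-style reconstructions who want
flux predictions at realistic, below-maximal growth rates, and at anyone
studying pathway-level energy/cost tradeoffs in small to mid-size networks.

## Worked example

The bundled glycolysis fixture converts 1 glucose to 2 lactate, producing
2 ATP, next to an ATP-maintenance/ATP-synthase/proton-transport balancing
set. A cost sweep from 50% to 100% of the ATP optimum:

```r
library(corsofba)

fx     <- make_glycolysis_fixture()
coeffs <- build_cost_coefficients(fx$model, fx$costs, cost_type = "combined")
aug    <- augment_model(fx$model, coeffs)

sw <- sweep_corso(aug, fx$medium, fractions = seq(0.5, 1, by = 0.1))
sw[, 1:4]
#> # A tibble: 6 × 4
#>   fraction status  objective_value total_cost
#>      <dbl> <chr>             <dbl>      <dbl>
#> 1      0.5 optimal           10.00      7754.
#> 2      0.6 optimal           12.0       9305.
#> 3      0.7 optimal           14.0      10856.
#> 4      0.8 optimal           16.0      12407.
#> 5      0.9 optimal           18.0      13957.
#> 6      1   optimal           20.0      15508.
```

The objective column is the ATP drain (2 ATP per glucose at uptake 10 gives
the optimum 20); `total_cost` is the minimal protein cost at each fraction,
non-decreasing in `f` because the feasible regions are nested.
`autoplot(sw)` draws the cost curve; `tidy(sw)` returns the reaction-level
fluxes.

The fundamental-pathway decomposition of the same network:

```r
paths <- fundamental_pathways(
  fx$model, fx$costs,
  currency_ids = c("atp", "adp", "pi", "h", "h2o", "nad", "nadh"),
  carriers = character(0), medium = fx$medium,
  glucose_exchange_id = "EX_glc")
tidy(paths)
#> # A tibble: 1 × 7
#>   pathway n_reactions is_internal_loop atp_potential total_cost cost_per_atp
#>     <int>       <int> <lgl>                    <dbl>      <dbl>        <dbl>
#> 1       1          14 FALSE                        2      1551.         775.
#> # ℹ 1 more variable: classification <chr>
```

All the full-model extreme pathways (core route plus any combination of the
balancing loops) collapse to **one** fundamental pathway whose imbalance is
+2 ATP, −2 ADP, −2 phosphate, +2 water per glucose — i.e. the decomposition
reads the net ATP yield of glycolysis directly off the reduced network —
and whose lactate yield is 2 per glucose. `recover_pathway()` adds the
removed loops back and returns an exactly balanced full-model flux vector.

A command-line front-end mirrors the R API
(`inst/cli/corso.R solve|sweep|pathways|compare|fixtures`), reading and
writing the same TSV/JSON formats.

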