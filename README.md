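# forespore

Two-cell metabolism-and-expression (ME) modeling of *Bacillus subtilis*
sporulation, in R.

During sporulation, asymmetric division produces a mother cell and a
smaller forespore whose metabolisms differentiate sharply: many of the
forespore's central-metabolic and biosynthetic enzymes are depleted, and
the mother cell nurtures it with building blocks through the
SpoIIQ–SpoIIIA (Q-A) channel that spans both cells. This package is for
systems biologists who want to model that interaction quantitatively:
which metabolites must cross the channel, which proteins are essential in
which cell, and which proteins lose all function when another is
depleted.

## The model

An ME model couples metabolism to the expression machinery that builds
its own catalysts. A reaction with flux $v$ catalyzed by $E$ consumes the
catalyst species at $(\mu/k_\mathrm{eff})\,v$, so the stoichiometric
matrix depends on the growth rate $\mu$ and growth maximization becomes

$$\max \mu \quad \text{s.t.}\quad S(\mu)\,v = 0,\qquad v^L \le v \le v^U ,$$

which the package solves by bisection over LP feasibility at fixed $\mu$
(the biomass lower bound is raised to the tested $\mu$). The two-cell
(ME2) model duplicates a single-cell model into mother-cell (`c`) and
forespore (`s`) compartments sharing one extracellular pool (`e`),
assembles the Q-A complex from its nine subunits, retargets the membrane
transport stoichiometries into channel reactions between the two
cytosols, applies sigma-factor partitioning (σ<sup>E</sup>/σ<sup>K</sup>
mother cell, σ<sup>F</sup> forespore), and optimizes only the forespore
formation rate. Depletions close translation reactions; essentiality,
protein inactivation and the sink-reaction blockage test are built on
top. The LP backend is a bounded-variable revised simplex written for
this package (no LP solver package is assumed), with structural
zero-propagation guards for the ill-conditioned coupling coefficients
that made the original genome-scale analyses need quad precision.

A deterministic toy sporulation model (~70 genes, ~250 reactions,
glutamate minimal medium) ships as first-class, tested code; see the
methods vignette (`vignettes/two-cell-me-models.Rmd`) for what it
emulates and what it deliberately does not.

## Worked example

```r
library(forespore)

single <- generate_toy_sporulation_model()          # deterministic toy model
veg    <- configure_medium(single, toy_glutamate_medium(single))
maximize_growth(veg)$mu_max
#> [1] 0.1123457                                     # vegetative growth, 1/h

two <- build_two_cell_toy(single)                   # mother cell + forespore
maximize_growth(two)$mu_max
#> [1] 0.047161102                                   # forespore formation rate

## forespore energy supply when ATP transport and its ATP synthase are off
shuttle <- build_two_cell_toy(single, scenario_flags(atp_transport = FALSE))
r <- maximize_growth(shuttle)
v <- parsimonious_solution(shuttle, r$mu_max); attr(v, "mu") <- r$mu_max
production_fractions(shuttle, v, "atp", "forespore")
#>   reaction       rate   fraction
#> 1   pgk_FS 0.38526224 0.65210164
#> 2   pyk_FS 0.19263112 0.32605082
#> 3 sucCD_FS 0.01290755 0.02184754
```

The forespore's ATP then comes from glycolytic substrate-level
phosphorylation (Pgk, Pyk) plus AKG oxidation through SucCD, with
fructose-6-phosphate imported from the mother cell and pyruvate plus
lactate returned — the glycolytic energy shuttle
(`channel_exchange_inventory(shuttle, v)` lists the traffic). Depleting
IlvC in the forespore (`dependency_analysis(shuttle, "ilvC",
cell = "forespore")`) inactivates the branched-chain pathway around it
and classifies IlvA and IlvD as blocked (no feasible route at all) but
AlsS as only inactive, since its acetolactate product can still escape
through the AlsD acetoin branch.

A thin command-line pipeline wraps the same functions:

```sh
Rscript inst/scripts/forespore-cli.R generate-toy --seed 1 -o toy.json
Rscript inst/scripts/forespore-cli.R solve toy.json
# mu_max  0.1123457
```

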