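---
title: "Two-cell metabolism-and-expression models of sporulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-cell metabolism-and-expression models of sporulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A metabolism-and-expression (ME) model couples a stoichiometric metabolic
network to the transcription and translation reactions that synthesize its
own catalysts. Enzyme demand enters through usage couplings: a reaction
carrying flux $v$ under catalyst $E$ with effective rate $k_\mathrm{eff}$
consumes the catalyst species at rate $(\mu/k_\mathrm{eff})\,v$, where
$\mu$ is the growth rate (h$^{-1}$). The stoichiometric matrix $S(\mu)$
therefore depends on $\mu$, and the growth-maximization problem

$$\max \mu \quad \text{s.t.} \quad S(\mu)\,v = 0,\; v^L \le v \le v^U$$

is nonlinear in $\mu$ but an ordinary LP at any fixed $\mu$. The package
solves it the standard way: bisection over LP feasibility, with the
objective (biomass) reaction's lower bound raised to the tested $\mu$ so
that feasibility of the LP decides attainability of that growth rate.

For sporulation the package builds a two-cell model: the single-cell
model is duplicated into a mother-cell copy (cytosol `c`) and a forespore
copy (cytosol `s`) sharing one extracellular pool (`e`). The two cytosols
are connected by the SpoIIQ–SpoIIIA (Q-A) channel complex, assembled from
the eight sigma-E-regulated spoIIIA subunits (mother cell) and
sigma-F-regulated SpoIIQ (forespore); channel transport reactions reuse
the single-cell membrane-transport stoichiometries, retargeted so that
template `e` species become mother-cell species and template `c` species
become forespore species (phosphotransferase-style templates therefore
pay their PEP on the receiving side). Only the forespore biomass is the
objective; mother-cell biomass keeps open bounds, which reduces the
two-growth-rate problem to one dimension. The forespore has no direct
membrane exchange with the medium: the engulfed cell is reached only
through the mother cell and the channel.

Sigma-factor partitioning closes sigma-E and sigma-K transcription units
in the forespore copy and sigma-F units in the mother-cell copy. Because
peptidoglycan synthesis is sigma-K regulated (mother cell only), the wall
precursor is granted an uncatalyzed integration reaction from the
mother-cell cytosol. Protein depletions — both the build-time forespore
depletion set and scan-time perturbations — are modeled by closing the
protein's translation reaction, which under the steady-state assumption
is equivalent to degrading the synthesized protein.

## Analyses

* **Essentiality** (`essentiality_scan()`): a protein (set) is essential
  in a context when no growth above the essentiality floor survives the
  closure of its translation reaction(s). The floor defaults to
  $\max(10^{-4}, 0.1\,\mu_\mathrm{wt})$; see *Numerical choices* for why
  it is a fraction of the wild-type rate. By monotone feasibility the
  call is decided by a single feasibility LP at the floor, warm-started
  from the wild type, which keeps proteome-scale scans fast.
* **Activity, inactivation and blockage** (`dependency_analysis()`):
  a protein's activity is its translation flux in the parsimonious flux
  distribution at $\mu_{\max}$. A wild-type-active protein that loses all
  translation flux after depleting another protein is *inactivated*. The
  *blockage* refinement adds a sink reaction ($\varnothing \to$ protein)
  with a tiny upper bound per candidate, fixes $\mu$, and maximizes the
  summed sink flux: a sink that cannot carry flux means no catalyzed
  route remains at all (blocked); a sink that fills its bound means the
  inactivity was merely optimal (inactive). An independent structural
  oracle (`oracle_protein_blocked()`) cross-checks every classification
  by iterative pruning over producibility *and* drainability — the
  backward direction is required because product accumulation (a dead-end
  downstream metabolite) also blocks a reaction.
* **Accounting** (`production_fractions()`, `protein_partition_ratio()`,
  `channel_exchange_inventory()`, `fold_enrichment()`): per-reaction
  production fractions of a metabolite in a cell, forespore:mother-cell
  translation-flux partition ratios binned as depleted (< 0.2), diluted
  (0.2–0.5) and enriched (> 0.5), net channel traffic with directions,
  and a generic hypergeometric fold-enrichment utility.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `k_eff` | 65 | h$^{-1}$ | metabolic/transport enzyme usage coupling |
| `k_channel` | 12 | h$^{-1}$ | Q-A channel usage coupling (conductance) |
| `k_trx`, `k_rib` | 50 | h$^{-1}$ | RNA polymerase / ribosome couplings |
| `k_mRNA` | 25 | h$^{-1}$ | mRNA usage coupling (degradation folded in) |
| `atp_per_residue` | 2 | mmol/mmol | translation energy cost |
| `glu_uptake` | 2 | mmol/gDW/h | glutamate uptake bound (minimal medium) |
| `inf_bound` | 1000 | mmol/gDW/h | finite sentinel for open bounds |
| bisection tolerance | $10^{-6}$ | h$^{-1}$ | absolute, on $[0, 2]$ |
| LP feasibility tolerance | $10^{-9}$ | – | double-precision contract |
| sink bound | $10^{-7}$ | mmol/gDW/h | 10 × LP feasibility tolerance |

The machinery rates and biomass composition were chosen once so that the
wild-type vegetative model grows near the canonical 0.1 h$^{-1}$ on
glutamate minimal medium with uptake bounded at 2 mmol/gDW/h. The channel
coupling is deliberately slower than metabolic enzymes: the Q-A conduit
is a single 9-subunit complex spanning two membranes, and pricing its use
realistically makes each cell prefer synthesizing what it can and reserve
the channel for what it cannot (nucleotides, sugars, and the amino acids
whose forespore pathways are depleted).

## What the toy generator emulates — and what it does not

`generate_toy_sporulation_model()` is first-class, tested code that
emulates, at ~70 genes and ~250 reactions, the pathway structure relevant
to the two-cell analyses: glutamate entry and AKG oxidation
(RocG, OdhAB–PdhD, SucCD), lower TCA, the citrate/Icd NADPH route, the
full gluconeogenesis/glycolysis shuttle enzyme set, lactate overflow,
lumped oxidative phosphorylation, de novo nucleotide synthesis with the
kinase ladder (Adk, Gmk, Cmk, PyrH, Ndk, PyrG), branched-chain amino-acid
synthesis (IlvA/IlvC/IlvD with AlsS on the acetolactate branch and the
AlsD acetoin escape), sigma-specific transcription units, the channel
genes, and membrane transport templates per species class.

Deliberate toy simplifications, each visible in the generator source:

* Charged-tRNA chemistry is collapsed into direct amino-acid consumption
  plus a fixed ATP cost per residue; mRNA turnover is folded into the
  `-mu/k_mRNA` coupling; transcripts are per transcription unit.
* Reversible catalyzed chemistry is split into forward/reverse reaction
  pairs sharing the catalyst (a signed net flux would let a backward flux
  *produce* its own enzyme through the usage coupling).
* The branched-chain reductoisomerase and the lumped threonine synthesis
  are modeled NADH-dependent, so the forespore branch draws on overflow
  reducing power; threonine synthesis is also modeled without an ATP
  step. These keep the forespore's branched-chain chain local in the
  parsimonious optimum, as observed for the full-scale system.
* Carrier directionality is curated: G/C/U nucleotide carriers and
  amino-acid permeases are concentrative importers, the ATP/ADP pair is
  translocase-style reversible, organic-acid carriers are reversible, and
  threonine and the branched-chain ketoacids have no carrier at all.
  Without the importer-only nucleotide carriers the forespore could
  "rescue" a mother-cell Gmk depletion by shipping GDP backwards — a
  route with no biological support.
* The built-in forespore depletion set is `{pckA, citZ, metE, aspB,
  rocG, alaT}` plus the absent ATP synthase: a toy-scale stand-in for
  the experimentally observed depletion of TCA and amino-acid enzymes.
  Leaving the glutamate-oxidation loop open would let the forespore
  re-absorb the very pyruvate surplus the shuttle exports.
* A synthetic UMP-to-CMP amination (`cmpA`) and a PyrH-type UMP kinase
  realize the observed redundancy in which either Cmk or PyrG alone
  still permits CTP synthesis while the double depletion does not.
* No elemental or charge balancing, no thermodynamics, no compartment
  volumes, no time resolution, no sigma-G regulon.

Passing tests on this generator demonstrate that the *pipeline* — model
construction, bisection solving, scans and accounting — behaves correctly
on a network with the right architecture; they do not certify predictions
for the genome-scale organism.

## Numerical choices

* **LP backend.** A dense bounded-variable revised simplex with a
  composite phase 1, eta-updated basis inverse, periodic
  refactorization, and Bland fallback, in double precision with a
  $10^{-9}$ feasibility tolerance. The original full-scale analyses used
  a quad-precision solver; double precision is a documented fidelity
  limit of this package, and the two guards below are its consequences.
* **Structural zero propagation.** ME LPs mix $O(1)$ stoichiometry with
  $O(\mu/k_\mathrm{eff})$ couplings, so within LP tolerance a "closed"
  translation still admits macroscopic catalyzed flux
  ($10^{-9}/10^{-7} = 10^{-2}$ units). Before every solve the assembler
  tightens bounds by exact reasoning iterated to a fixpoint (dead species
  close their consumers; dead catalysts close their reactions at
  $\mu > 0$). The propagation only removes flux patterns infeasible in
  exact arithmetic and is recomputed from current bounds, so reopening
  reactions (the naive model) needs no special handling.
* **Essentiality floor.** Expression-machinery fluxes scale roughly with
  $\mu^2/k$, so near $\mu = 10^{-4}$ they sink below any double-precision
  tolerance and feasibility cannot be certified. The floor is therefore a
  resolvable fraction (10%) of the wild-type rate; in growth-coupled toy
  models depletion outcomes are structural (near-wild-type growth or
  none), so the classification is insensitive to the floor's position
  within $(0, \mu_\mathrm{wt})$.
* **Sink test slack.** At exactly $\mu_{\max}$ the feasible set is
  numerically a point and sink maximization is vacuous; the blockage
  stage runs at $\mu_{\max}(1 - 10^{-4})$. Classifications are stable
  over slacks between $10^{-4}$ and $10^{-2}$ and agree with the
  structural oracle.
* **Degenerate optima.** All reported flux summaries use the
  parsimonious (minimum total |flux|) solution via the standard
  split-variable LP, making activities, ratios and inventories
  deterministic. Ties inside the parsimonious optimum are resolved by the
  solver's deterministic pivoting, so repeated runs agree exactly.
* **Two-stage reading of the sink objective.** The literal combined
  objective "growth plus sink sum" is numerically meaningless when sink
  bounds sit near solver tolerance; growth is maximized first
  (bisection), then the sink sum at fixed $\mu$, which is the
  lexicographic limit of the combined objective.

## Known limitations

* Double-precision LP: quantities within ~$10^{-9}$ of a bound are not
  distinguishable, and the ill-conditioning guards above are required.
* The toy model's percentages (ATP fractions, partition ratios) are
  architectural, not quantitative predictions for the organism.
* The channel "open pore" is a single conductance parameter; no
  per-species selectivity and no time-resolved channel closure.
* Essentiality at the floor equates "essential" with "no growth above
  10% of wild type"; graded fitness defects are out of scope.
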