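---
title: "Enzyme-constrained flux analysis with ecflux: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enzyme-constrained flux analysis with ecflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecflux)
```

## The model

A constraint-based metabolic model is a stoichiometric matrix $S$
(metabolites $\times$ reactions) with flux bounds $l \le v \le u$ and an
objective reaction, typically biomass synthesis. Flux balance analysis (FBA)
solves the linear program

$$\max_v \; v_{\text{objective}} \quad \text{s.t.} \quad S v = 0,\; l \le v \le u,$$

with fluxes in mmol/gDW/h and the biomass flux read as the specific growth
rate in 1/h. Plain FBA knows nothing about the cost of expressing the
enzymes that carry those fluxes, which is why it predicts growth rising
linearly with substrate availability forever.

An enzyme-constrained model (ecGEM) adds a single proteome-allocation row.
An enzymatic reaction running at flux $v_i$ needs at least
$v_i \, \mathrm{MW}_i / (\sigma_i \, k_{cat,i})$ grams of enzyme per gram
dry weight, and the total is bounded by the protein pool available to
metabolism:

$$\sum_i \frac{v_i \, \mathrm{MW}_i}{\sigma_i \, k_{cat,i} \cdot 3600}
  \;\le\; p_{tot} \cdot f .$$

Units: $v_i$ in mmol/gDW/h, $\mathrm{MW}_i$ in kDa (g/mmol), $k_{cat,i}$
stored in 1/s and converted to 1/h by the factor 3600, so each term is in
g enzyme/gDW. The parameters and their defaults:

* `ptot` — total protein mass fraction of dry weight; default 0.4653 g/gDW, a
  measured value typical of thermophilic filamentous fungi.
* `f` — fraction of total protein that is metabolic enzyme, estimated from
  quantitative proteomics as the model-protein share of proteome mass
  (`enzyme_mass_fraction()`); default 0.55. The product
  `ptot * f = 0.255915` g/gDW is the pool bound.
* `sigma` — effective saturation of each enzyme, i.e. how much of its
  $k_{cat}$ capacity is realized in vivo; uniform 0.5 by default, stored
  per entry so calibration can act on $k_{cat}$ alone.
* kcat sources are tagged (`database`, `turnup_predicted`, `dl_predicted`,
  `imputed`, `calibrated`) and merged by a priority order in which measured
  database values outrank predictions and calibrated values outrank
  everything; reactions with no record receive the median of the covered
  values (`merge_kcat()`).

Before the pool row is added, the model is normalized the way ecGEM
pipelines expect (`split_model()`): every reversible reaction becomes a
forward/reverse pair of irreversible reactions (`<id>_reverse`, negated
stoichiometry), and every reaction catalyzed by isozymes (an `or` in its
gene–protein–reaction rule) is segregated into one copy per isozyme
(`<id>_num1`, `<id>_num2`, ... in the textual order of the conjuncts), each
carrying one `and`-complex whose molecular weight is the subunit-count
weighted sum of subunit MWs. Both transformations are idempotent and
preserve the feasible net-flux set; `net_fluxes()` maps any split solution
back to original-model net fluxes.

## The LP core

No linear-programming backend is assumed: the package carries a dense
two-phase primal simplex (`solve_lp()`). The LPs here are small (tens to a
few hundred variables) but systematically degenerate, because every
steady-state row has a zero right-hand side. The implementation therefore
uses a Dantzig entering rule with an automatic switch to Bland's rule after
500 pivots without objective improvement, which guarantees finite
termination on degenerate problems; the leaving-variable tie-break is the
smallest basis index. Pivoting tolerance is 1e-9; tests assert agreement
with an independent interior-point/dual-simplex implementation to 1e-7 and
solution feasibility to 1e-6. Variable ordering is fixed by the model, so
every solve is deterministic.

pFBA is implemented lexicographically: first the objective LP, then a
second LP that fixes the objective flux at its optimum (as a bound, which
is exact — the objective is a single variable) and minimizes the total
flux. On split models all fluxes are non-negative, so the second stage is a
plain sum. Reversible input models are split internally and reported as net
fluxes.

Flux variability analysis (`fva_raw()`) solves two LPs per reaction with
the objective held at `fraction_of_optimum` times its maximum (default
1.0, fixed exactly rather than with a relaxation factor, which keeps the
ranges clean of amplified round-off). Aggregation to original reactions
(`aggregate_variability()`) applies, in order: within each direction the
maximal range over isozyme copies; across directions the reverse-copy
range is subtracted from the forward range. A negative difference is
clamped to zero (a variability measure cannot be negative) and logged when
it exceeds 1e-9. Because the subtraction rule is a convention rather than
a theorem, an alternative `rule = "net"` reports the range of the net flux
implied by independent per-copy ranges (the sum of the two directional
ranges); the directional rule is the default.

## Phenotype phase planes and the metabolic-adjustment scan

`phpp()` evaluates pFBA growth over a grid of substrate and oxygen uptake
bounds (infeasible cells are 0). `adjustment_scan()` sweeps the substrate
uptake — fixed exactly at each rate, since overflow phenomena only appear
when the cell must process the carbon it imports — and reports per point:

* biomass yield $v_{bio} / (v_{sub} \cdot \mathrm{MW}_{sub})$ in gDW per g
  substrate (recorded as 0 with a flag at zero uptake);
* enzyme efficiency for biomass $\varepsilon_{bio} = v_{bio} / E_{min}$,
  where $E_{min}$ is the minimum total enzyme supporting that biomass flux
  (`min_enzyme_solution()`) with the substrate merely *available* at the
  scanned rate. Total minimized enzyme is used rather than a
  biomass-pathway-only subset, since pathway membership is not well defined
  in a coupled network;
* energy-synthesis enzyme cost $\sum_i E_i / v_{ATP,i}$ over reactions that
  produce ATP in the direction they carry (net generated ATP per reaction =
  stoichiometric ATP coefficient times flux);
* the share of ATP produced by user-designated oxidative-phosphorylation
  reactions (explicit designation avoids fragile pathway auto-detection);
  undefined (NA) where no ATP is produced, e.g. at zero uptake;
* a stage label: `substrate_limited` while the pool row has slack
  (> 1e-6 g/gDW), `metabolic_overflow` once any designated overflow
  exchange secretes (> 1e-6 mmol/gDW/h), `metabolic_adjustment` in
  between. Slack and secretion thresholds are used instead of dual values
  for robustness.

The default sweep is 0–6 mmol/gDW/h in 61 steps.

## Substrate hierarchy from precursor enzyme efficiencies

For each carbon source, the uptake bound is set to an equal-carbon basis of
15 mmol C/gDW/h divided by the substrate's carbon count (glucose 2.5,
cellobiose 1.25, xylose and arabinose 3.0, galactose 2.5). Each of the 12
biomass precursors (G6P, F6P, G3P, 3PG, PEP, PYR, AcCoA, OAA, AKG, SUCC,
E4P, R5P) receives in turn a temporary unit drain — enzyme-free, outside
the pool row — whose flux is maximized; the minimum total enzyme at that
flux gives the efficiency $\varepsilon = v / E_{min}$. Unreachable
precursors are recorded as $\varepsilon = 0$ with a flag.

Substrate a is preferred over b iff $\varepsilon(a, p) > \varepsilon(b, p)$
strictly for *every* precursor $p$; any mixed or tied comparison means
co-utilization. Tiers are built by repeatedly extracting the substrates not
strictly dominated by any remaining substrate, so co-utilized substrates
share a tier.

## kcat calibration

Both procedures only raise kcats (they relax the pool constraint), cap them
at 1e6 1/s, tag them `calibrated`, and log every step.

*Enzyme-usage method* (`calibrate_enzyme_usage()`): while pFBA growth is
below `target_growth * (1 - growth_tol)`, multiply the kcat of the reaction
with the largest enzyme-usage share by `factor` (default 2, ties broken by
reaction id). If a step overshoots the target band, the step size is
bisected — growth is monotone in any single kcat, so the bisection lands the
calibrated model within ±`growth_tol` of the target. The loop stops on
convergence, `max_iter`, or stagnation (three consecutive iterations with
no growth improvement), the latter two flagged in the step log rather than
raised.

*13C-consistency method* (`calibrate_c13()`): measurements are net
original-model fluxes (via `net_fluxes()`), compared by relative error with
an absolute guard of 1e-6 mmol/gDW/h in the denominator. Per iteration, one
under-predicted measurement outside tolerance is fixed: the one whose
enzyme-cost-dominant split copy consumes the largest share of the pool in
the current solution. Selecting by realized usage targets the actual
kinetic bottleneck; error-ranked selection was found to chase downstream
reactions whose flux cannot recover until an upstream bottleneck is fixed,
and bump-everything variants permanently over-relax enzymes whose
under-prediction is collateral (kcats cannot be lowered again).
Over-predicted fluxes are never corrected downward: the pool row is an
upper bound, so over-prediction signals objective or network structure, not
kcat. The adjustment magnitude and stopping rules are this package's
choices; the upstream literature reports calibrated values without
specifying them.

## Engineering-target prediction

*Method 1* (`targets_top_cost()`): maximize the product by pFBA, aggregate
per-reaction enzyme usage to genes — a complex's usage is split among member
genes by subunit mass share, since the ranking is per protein while the
pool row is per reaction — and return the top `n` (default 15) as
overexpression candidates.

*Method 2* (`targets_hglp_lghp()`): compare a high-growth/low-product state
(biomass fixed at 100% of its maximum, product maximized as secondary
objective) with a low-growth/high-product state (biomass at 10%). The
acronym expansion fixes which state is which; reactions with flux above
1 mmol/gDW/h in either state are candidates, classified enhance if their
enzyme cost (or, for enzyme-free reactions such as transporters, their
flux) is higher in the low-growth/high-product state, weaken if lower.

## The minicore fixture

`make_minicore()` generates a fixed, fully deterministic central-carbon
network (36 reactions, 30 metabolites, 27 gene products; 49 reactions after
splitting) that stands in for a genome-scale fungal model. It is a
caricature built from lumped reactions, engineered so that the phenomena
the methods are meant to expose actually exist in it and are asserted by
the test suite:

* **Five sugars.** Glucose and galactose are hexoses (galactose enters via
  a Leloir-style kinase to glucose-1-phosphate plus phosphoglucomutase, one
  extra enzyme); cellobiose has a hydrolytic route (two ATP per
  disaccharide) and a phosphorolytic route (one ATP, via
  glucose-1-phosphate); xylose enters the pentose pool directly; arabinose
  needs two enzymatic steps through an arabitol-like intermediate.
* **Respiration vs fermentation.** Oxidative phosphorylation is a
  1000-kDa three-subunit complex with a low turnover — high ATP yield per
  carbon but high enzyme mass per flux. An alternative oxidase (AOX,
  30 kDa, fast) re-oxidizes NADH without making ATP, as fungal alternative
  respiration does. Ethanol fermentation (PDC + ADH) is redox-neutral,
  ATP-poor and enzyme-cheap. Oxygen uptake is capped at 12 mmol/gDW/h — a
  finite respiratory capacity.
* **Three growth stages.** With rising (forced) glucose uptake the optimum
  passes through: carbon limitation with slack pool (growth linear in
  uptake); pool saturation at ~2.7 mmol/gDW/h, where NADH disposal shifts
  from the expensive ATP-coupled complex to AOX (yield falls, biomass
  enzyme efficiency rises, the oxidative-phosphorylation ATP share falls);
  and, once respiration hits the oxygen ceiling near 5 mmol/gDW/h, ethanol
  overflow. The adjustment-before-overflow window exists precisely because
  replacing oxidative ATP by AOX-respired carbon is cheaper per unit of
  enzyme than fermentation as long as oxygen lasts.
* **Designed hierarchy.** With enzyme prices as shipped, the efficiency
  matrix yields the tiers {cellobiose, glucose} > {galactose, xylose} >
  {arabinose}: the phosphorolytic ATP saving makes cellobiose the better
  source for ATP-expensive precursors while glucose's cheaper entry wins
  the ATP-generating ones (co-utilization); galactose and xylose each win
  on "their" side of the hexose/pentose divide because the
  transketolase/transaldolase interconversion carries a deliberate enzyme
  cost that taxes both crossing directions; arabinose loses everywhere.
* **Designed targets.** Maximizing ethanol ranks the decarboxylase and
  dehydrogenase genes among the top enzyme costs, and the
  high-growth/low-product comparison labels the fermentation branch
  enhance and the respiratory reactions weaken.

The 13C fixture condition is glucose at 2.4 mmol/gDW/h, just below pool
saturation: real 13C flux measurements come from carbon-limited cultures,
and in that regime the pFBA flux distribution is determined by
stoichiometry rather than enzyme prices, which is what makes
perturb-then-recalibrate recovery well-posed. The measured set covers
carbon-backbone fluxes only — 13C metabolic flux analysis cannot observe
cofactor turnover or oxidative phosphorylation directly.

What the fixture does *not* emulate: compartments, a second redox currency
(NADPH), maintenance ATP, thermodynamics, kinetic regulation, and realistic
flux magnitudes. Passing tests demonstrate that the implementation
reproduces the qualitative physics of proteome allocation on a network
where the ground truth is known by construction — not that it reproduces
any genome-scale model's numbers.

Biomass draws all 12 precursors plus 24 ATP per unit growth, with
coefficients scaled so growth rates land in the 0.05–0.5 1/h range typical
of filamentous fungi. The lumped 2-oxoglutarate step carries half a
substrate-level ATP, standing in for the succinyl-CoA synthetase share of
the real pathway.

## Other generators

`make_random_toy()` builds a connected random model around a guaranteed
backbone (substrate exchange, chain, biomass drain), so every seed yields a
feasible model with positive optimum. `synth_proteome()` plants an exact
enzyme mass fraction by scaling background-protein abundances, which makes
the recovery test sharp to numerical precision. `perturb_kcats()` and
`synth_c13_fluxes()` (log-normal multiplicative noise, tolerance
`max(2 * cv, 0.05)`) record their ground truth before perturbing. All
generators take explicit seeds and restore the caller's RNG state.

## Numerical choices and problem sizes

Feasibility and optimality are requested at 1e-9 and asserted at 1e-6
throughout; pool-feasibility slack of 1e-6 g/gDW and flux thresholds of
1e-6 mmol/gDW/h define "binding" and "secreting" in stage detection. The
shipped analyses use desk-scale problems: 49 split reactions, 61-point
sweeps, 21x21 phase-plane grids, 20-seed recovery batteries — all solvable
in seconds on one CPU, which is also the regime in which the dense tableau
simplex is an appropriate backend.

## Limitations

The simplex is dense and O(rows x columns) per pivot: adequate up to a few
hundred reactions, not for genome-scale models, where a sparse LP backend
should replace `solve_lp()` behind the same interfaces. SBML support covers
Level 3 FBC bounds, objectives and gene associations only. The directional
variability-aggregation rule can understate the range of a reversible
reaction's net flux; use `rule = "net"` where that matters. Calibration is
greedy and monotone by design; it will not undo an over-relaxed kcat.
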