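---
title: "Community FBA for syngas co-cultures: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community FBA for syngas co-cultures: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncomfba)
```

## The modeling problem

Syngas fermentation couples a CO/H2-consuming acetogen (Wood–Ljungdahl
pathway, producing acetate and ethanol) with partner organisms that upgrade
those products: a propionigen converting ethanol + CO2 to propionate and
acetate via the acrylate route, and a chain elongator extending carboxylates
two carbons at a time with ethanol as the electron donor (reverse
beta-oxidation), yielding even-chain C4/C6 acids from acetate and odd-chain
C5/C7 acids when propionate is available. `syncomfba` implements the
community-scale constraint-based analysis of such a tri-culture:

* assemble single-species stoichiometric models into one community model
  with species-tagged cytosols and a shared extracellular pool;
* run community flux balance analysis (cFBA) under chemostat-style
  constraints, where the dilution rate equals the common growth rate and
  species abundances are fixed ratios;
* map the feasible region over species-ratio x growth-rate grids;
* characterize product distributions by uniform sampling of the flux
  polytope rather than single optima;
* reproduce the surrounding bioprocess arithmetic (dilution rates, gas
  conversions, carbon/electron balances, undissociated-acid fractions).

## The cFBA formulation

A model is a stoichiometric matrix $S$ (metabolites x reactions) with flux
bounds $l \le v \le u$. FBA solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; l \le v \le u .$$

For a community at steady state in a chemostat, specific bounds
(mmol gCDW$^{-1}$ h$^{-1}$) are converted to *environmental* bounds
(mmol h$^{-1}$) by multiplying every finite per-species bound by
$X f_i$, where $X$ is total biomass (g) and $f_i$ the species'
cell-dry-weight fraction. Species biomass fluxes are fixed to
$f_i X \mu$ and the community biomass flux to $X \mu$; the community
biomass reaction consumes $f_i$ grams of each species-biomass
pseudo-metabolite per gram of community biomass, which makes the two
constraints consistent by construction (`apply_condition()`,
`add_community_biomass()`). Bounds at or beyond the sentinel magnitude
(1000 by default) are treated as "unbounded" and never scaled — scaling a
sentinel would silently turn it into a binding constraint.

A condition is *feasible* when the LP has an optimal solution. Because all
constraints are affine in $\mu$, the feasible set of growth rates at fixed
fractions, biomass and feed is convex — an interval. The test suite asserts
this contiguity on every scanned grid row; it is also why feasibility
regions in ratio x growth-rate maps are contiguous bands.

### The LP solver

No linear-programming backend is part of this package's dependency stack,
so the LP is solved by an internal bounded-variable two-phase revised
simplex (dense algebra, Dantzig pricing with a switch to Bland's rule after
a run of degenerate pivots, artificial variables pinned to zero after phase
one so that the rank-deficient rows typical of stoichiometric matrices are
harmless). Every reported optimum is revalidated against $Sv=0$ and the
bounds at $10^{-6}$; a solution failing validation is reported as a solver
failure, never silently. The solver is tested against an independent
brute-force vertex-enumeration oracle on small networks (agreement to
$10^{-8}$) and on randomized LPs including rank-deficient and
fixed-variable cases.

### Flux sampling

Product claims are made on sampled flux distributions, not single FBA
optima, because alternate optima are ubiquitous in community models. The
sampler is artificial-centering hit-and-run (ACHR) on
$\{v : Sv = 0, l \le v \le u\}$:

1. *Warm-up*: flux-variability analysis (min/max LP per free reaction)
   supplies well-spread polytope vertices and, as a side effect, identifies
   fluxes that are numerically determined (zero FVA width) even though they
   lie in the null space of $S$ — such coordinates are frozen, otherwise
   chord lengths collapse and the chain stalls.
2. *Chain*: directions are differences between randomly chosen warm-up
   vertices and a running center over all accepted points; the step is
   uniform on the feasible chord. The chain is thinned (default: keep every
   100th point) and reprojected onto the equality subspace every 25 steps
   via the SVD of the constraint matrix, so numerical drift never
   accumulates.
3. *Validation*: every kept sample is checked against $Sv=0$ and the bounds
   at $10^{-6}$; the run aborts rather than return invalid points.

Sampling is seed-deterministic: the same seed, model and parameters give a
bitwise-identical sample matrix. On a one-dimensional polytope the chain
reduces to exact uniform draws, which the tests exploit (mean at the
midpoint, sd $w/\sqrt{12}$).

## The toy community

`make_toy_acetogen()`, `make_toy_propionigen()`,
`make_toy_chain_elongator()` and `make_toy_triculture()` generate a small,
fully element-balanced three-species community so that every pipeline stage
runs without downloading genome-scale models. Design choices:

* **Lumped electron carrier.** Ferredoxin/NAD(P)H pools are collapsed into
  one reduced equivalent `red` carrying 2 electrons (elementally H2).
  Community-level conclusions depend only on net electron balance.
* **ATP as an element-free token.** ATP yields are embedded in the
  catabolic lumps (acetate kinase 1 ATP per acetate, ethanol branch 0.5,
  acrylate lump 1, ethanol oxidation 1; all configurable). A free-standing
  `[H] -> ATP` reaction would form a perpetual-motion cycle with the
  hydrogenase, so it is deliberately absent.
* **Biomass.** Composition CH$_{1.8}$O$_{0.5}$N$_{0.2}$ (stored x10 as
  C10H18O5N2, molar mass about 246 g/mol, about 24.6 g per C-mol), with
  ammonia as nitrogen source. Biomass reactions are scaled so one flux unit
  produces 1 g CDW h$^{-1}$, which makes the chemostat constraints read
  directly in grams.
* **Maintenance.** NGAM defaults to 0.3 mmol ATP gCDW$^{-1}$ h$^{-1}$
  (a modest anaerobic value) as a lower bound on ATP hydrolysis; GAM is
  40 mmol ATP per g biomass, a typical genome-scale figure.
* **Uptake capacities.** CO transport is capped at 20 mmol gCDW$^{-1}$
  h$^{-1}$, H2 at 30, organic substrates at 10. The CO cap is the
  load-bearing one: total CO processing scales with acetogen biomass, so
  communities with little acetogen cannot meet a forced CO uptake — the
  mechanism that bounds the feasible region of the chemostat grid. The
  defaults keep the paper-style conditions (total biomass 0.32 g, CO
  exchange between -3.5 and -1 mmol h$^{-1}$, growth rates up to
  0.08 h$^{-1}$) partly feasible and partly infeasible, which is what a
  feasibility scan needs to be informative.
* **Stoichiometric checkpoints.** Every internal reaction is element
  balanced (C, H, O, N), checked by `check_elemental_balance()` in the test
  suite, and every catabolic lump closes its degree-of-reduction balance
  ($\gamma = 4C + H - 2O$, $\sum_j \gamma_j s_j = 0$). Hand-checkable
  identities pinned in tests include: CO-only acetogenesis
  (4 CO + 2 H2O -> acetate + 2 CO2), the zero-CO2 limit at a CO/H2 uptake
  ratio of 0.5 (all carbon to ethanol, acetate and CO2 exactly zero), the
  2:1 propionate:acetate ratio of the pure acrylate route (tunable down
  through 1.2:1 by mixing in ethanol oxidation), and 1:1
  ethanol:acetate consumption in butyrate elongation.

What the toy does *not* emulate: genome-scale redundancy (thousands of
alternate routes), realistic maintenance magnitudes fitted to chemostat
data, thermodynamic or kinetic limits, and product inhibition. Passing
tests on the toy therefore demonstrate that the pipeline's mechanics —
assembly, constraint conversion, LP, sampling, mass balances — are correct,
not that genome-scale predictions would be quantitatively reproduced.

### An emergent subtlety worth knowing about

In the merged toy community, the partners' ethanol oxidation evolves H2
into the shared pool, and the acetogen's hydrogenase can re-consume it as
reducing power. As a result the acetogen's *absolute* maximum ethanol
output grows slightly with partner abundance, while ethanol availability
*per gram of partner biomass* increases with the acetogen fraction — the
quantity the scenario test asserts. This is a genuine feature of H2-cycling
syntrophy, not an artifact.

## Scenario analyses

`scan_feasibility()` maps feasibility over a fraction lattice (default step
0.1) times a growth-rate grid; `scan_ratios()` samples the product profile
at fixed growth rate across biomass ratios; `scan_h2()` varies H2
availability at fixed CO bounds. H2 levels are interpreted by default as
uptake *capacities* (exchange bounds `[level, 0]`), matching how the CO
feed is constrained as an interval; a `"fixed"` mode pins the flux exactly.
Under growth with maintenance, forcing H2 uptake at twice the CO uptake is
stoichiometrically infeasible in the toy (biomass synthesis diverts the
acetyl acceptor pool), which is the practical reason the capacity reading
is the default — the zero-CO2 limit itself is reproduced exactly in
catabolic mode (no growth, no maintenance), where the flux solution is
unique.

Problem sizes used in the packaged checks: toy triculture (74 reactions, 56
metabolites), 36-point ratio lattice x 16 growth rates for the grid,
sampling chains of 400–2000 kept points with thinning 10–30. These run in
seconds to a couple of minutes on a single CPU.

## Bioprocess calculators

The chemostat layer implements: $D = 1/\mathrm{HRT}$; ideal-gas conversion
of gas flows at *explicitly supplied* temperature and pressure (no hidden
STP convention — a reported consumption percentage is only reproducible
under a stated convention; 0 degC and 101.325 kPa turn 4 mL min$^{-1}$ of
70% CO into 7.50 mmol h$^{-1}$); consumption percentages; steady-state
rates $D V (c_{out} - c_{in})$ plus optional gas terms;
Henderson–Hasselbalch undissociated fractions
$1/(1 + 10^{\,pH - pK_a})$ with per-acid pK$_a$ values shipped alongside
the average-acid convention (4.83); degree of reduction
$\gamma = 4C + H - 2O - 3N$ (NH3 reference state for nitrogen); and
carbon/electron balance recoveries, which are scale-invariant and additive
over balanced reactions. `simulate_chemostat_observations()` generates
noisy steady-state records (multiplicative Gaussian noise on
concentrations) to exercise rate recovery; with 5% noise and 20 records the
configured rate is recovered within three standard errors.

## Numerical choices and degenerate inputs

* LP tolerances: reduced-cost and pivot tolerances $10^{-9}$/$10^{-10}$,
  feasibility validation $10^{-6}$; infinite bounds are clamped to
  $\pm 10^6$ (FBA convention treats magnitudes ~1000 as unbounded anyway).
* Ties among alternate FBA optima are reported as the solver's vertex
  as-is; all flux-level claims in scans rest on sampling means.
* Zero-dimensional polytopes (fully determined models) are sampled as the
  unique point; infeasible models error before sampling.
* Merging species with conflicting formulas for a shared extracellular
  metabolite is an error naming the metabolite; duplicate exchange
  reactions merge with union-interval bounds, so a community is never more
  restricted than any member (override by setting explicit bounds in the
  condition).
* `apply_condition()` stashes the original specific bounds on first use and
  always rescales from that stash, so applying a condition twice equals
  applying it once.

## Limitations

The sampler targets distributional agreement, not sample-for-sample
identity with any external implementation. The simplex is dense and
suitable for networks up to a few thousand reactions; genome-scale models
load and solve, but a sparse-factorization backend would be preferable for
routine genome-scale sampling. The toy community's quantitative rates are
of the right order for a 0.32 g chemostat culture but are not fitted to any
organism; only the hand-derivable stoichiometric identities above are
asserted as exact.
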