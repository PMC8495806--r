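---
title: "Methods: steady-state energy flux in trophic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steady-state energy flux in trophic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophicflux)
```

## The model and its assumptions

`trophicflux` computes the steady-state energy flux along every feeding link
of a trophic network from the metabolism-centred balance: the assimilated
intake of every consumer equals its own metabolic demand plus what its own
consumers take out of it. Per link, flux out of a resource node is

$$F = \frac{X + L}{e_a}$$

with $X$ the metabolic demand, $L$ the loss to consumption by higher levels,
and $e_a$ the assimilation efficiency. Network-wide, writing $G_c$ for
consumer $c$'s total consumption and $W$ for the column-normalized diet-share
matrix (resources in rows, consumers in columns), the balance is linear:

$$\bar e_c\,G_c - \sum_k W[c,k]\,G_k = X_c, \qquad
  \bar e_c = \sum_r e_r\,W[r,c]$$

under resource-level efficiencies (the mixed-diet case: the effective
efficiency of a consumer is the diet-share-weighted mean of its resources'
efficiencies), or $e_c G_c$ under consumer-level ones. Basal nodes carry
$G = 0$: the system is assembled over consumers only, which keeps it
nonsingular for webs whose basal pools have no modelled intake — energy
flowing *into* plants or detritus is deliberately outside the balance.

The assumptions that matter:

* **Steady state.** In- and outflux balance at every node; there is no
  time-resolved dynamics and no biomass turnover term. (The
  death-rate/production variant of flux calculation is out of scope.)
* **Minimum flux.** Demands are typically basal metabolic rates, so computed
  fluxes are the minimum required to keep the community alive. Field rates
  run roughly a factor of three higher; `node_losses(fmr_multiplier = 3)`
  applies that uniformly, but its effect on fluxes is web-shaped, not a
  simple rescaling of conclusions.
* **Fixed topology and preferences.** Links and active weights are inputs;
  the package infers neither from traits nor from molecular data.

## Solvers and numerical choices

Two independent routes produce the same answer and cross-check each other:

* `solve_fluxes()` assembles the linear system over consumers and calls the
  dense LAPACK solver. It handles omnivory and trophic loops (mutual
  predation, actively down-weighted cannibalism). A singular system is
  reported as structural infeasibility; any negative consumption is an
  error naming the offending nodes, never a silent clamp — negative flux has
  no physical meaning and signals bad inputs.
* `solve_fluxes_sequential()` walks the topological order from the top
  consumers downward, accumulating each node's loss to consumption — the
  by-hand procedure. It refuses cyclic webs and serves as the oracle in the
  test suite: on randomized guild webs the two agree to ~1e-15 relative,
  asserted at 1e-10.

Tolerances: consumer balance residuals (`balance_residuals()`, relative to
$\max(X_c, 10^{-12})$) are asserted at 1e-9 in tests and sit at machine
precision in practice. Consumption values below 1e-14 of the largest are
snapped to zero before the feasibility check so that structurally zero
consumers do not trip the negativity error. Because the system is linear in
$X$, scaling all losses by a power of two reproduces fluxes bitwise; other
scalings agree to ~1e-15.

## Parameters, units, defaults

* **Assimilation efficiencies** (dimensionless, in (0, 1]): bundled defaults
  by resource type at a 20 °C reference — detritus 0.158, plant 0.545,
  animal 0.906 (Lang et al. 2017 averages for terrestrial arthropod webs).
  Resource-level assignment is the default because mixed-diet consumers
  digest a detritus meal and an animal meal very differently; consumer-level
  assignment (one efficiency per consumer, keyed by guild) is supported for
  parity with common software interfaces. Efficiencies are known to rise
  with temperature and diet nitrogen; because no canonical formula belongs
  in the main data path, temperature dependence is a pluggable hook
  `function(e, delta_T)` with identity default — the package does not invent
  an equation, it keeps the interface stable for users who bring one.
* **Metabolic regressions**: $\ln X = \ln x_0 + a \ln M - E/(kT)$ with
  $k = 8.62\times10^{-5}$ eV/K, temperature converted to Kelvin internally
  (all interfaces take °C — a deliberate guard against the classic unit
  slip). The log convention of every length–mass regression is an explicit
  field (`log10` vs `ln`), never inferred, because published regressions
  routinely omit it. Bundled coefficients are editable placeholder data with
  provenance columns, not code; they should be replaced with values verified
  against the cited sources for real analyses.
* **Units** are opaque coherent tags (`mass`, `area`, `energy`, `time`;
  defaults mg, m², J, h). Nothing is converted automatically; if losses are
  J/h and biomass mg/m², fluxes are J/m²/h.
* **Losses basis**: per-unit-biomass losses (the common literature form) are
  multiplied by node biomass before solving; `node_losses()` always emits
  whole-node values and flips the flag.

## Size structure

Per-capita metabolic rate is concave in body mass ($0 < a < 1$), which has
two distinct consequences that are easy to conflate:

* A population of many small individuals demands **more** than one organism
  holding the same cumulative biomass: $\sum_i m_i^a \ge (\sum_i m_i)^a$.
  This is the reason body-size structure matters at all, and it is asserted
  property-style in the tests.
* The mean-mass shortcut $n\,\bar m^a$ **over**estimates the demand of an
  unequal-mass population relative to the individual-level sum
  ($\sum_i m_i^a \le n \bar m^a$ by Jensen's inequality, equality iff all
  masses are equal). `node_losses()` therefore warns whenever it falls back
  to mean mass × abundance, and prefers individual body-mass lists.

## Preferences

Realized diet shares combine active choice weights $w$ with passive,
encounter-driven availability: $W[r,c] = w_{rc} B_r / \sum_{r'} w_{r'c}
B_{r'}$ (biomass mode), or normalized active weights alone, which with equal
weights reduces to the uniform null assumption. Cannibalistic self-links
require an explicit active weight at construction time: under passive
preferences a cannibal's own (often large) biomass would silently dominate
its diet, so the package refuses to default that weight. Omnivores
over-weighted toward overabundant plant/detritus pools are handled by the
same generic mechanism — lower the active weight — rather than a special
case, and any such adjustment deserves a caveat in downstream write-ups
when herbivory/detritivory comparisons are the point of the study.

## Aggregation

`aggregate_nodes()` merges compartments: biomasses, abundances, and
whole-node losses are summed (per-biomass losses combine as biomass-weighted
means, conserving group totals exactly); individual body masses concatenate;
links rebuild as the union of member links. Where the literature gives no
rule for combining active weights of merged links, this package uses the
consumer-biomass-weighted mean of member weights and records that choice in
the result's `aggregation` attribute. Merges are classified: *parallel*
(members share resource and consumer sets outside the group) is quiet and —
as the tests assert on fully guild-connected synthetic webs — leaves
guild-level function fluxes unchanged to 1e-6 relative; *serial* (a member
eats another member) always warns, the intra-group links are dropped, and
results downstream should be treated with suspicion. Note the exactness
claim needs genuinely parallel partitions: merging guild members with
*different* diets redistributes losses among their prey and does change
function fluxes.

## Sensitivity analysis

`perturb_and_recompute()` multiplies one parameter family (losses,
efficiencies, or preferences) elementwise by independent factors
$1 + v\,u$, $u \sim \mathrm{Uniform}(-1, 1)$, re-solves, and reports
per-link/per-node mean relative deviations and coefficients of variation.
Choices the literature leaves open, made once here: the noise is uniform and
multiplicative; preference perturbation is link-wise followed by column
re-normalization; perturbed efficiencies are clamped into (0, 1] with clamp
events counted in the report. Drawing the $u$ field once per seed (and
scaling by $v$) makes the stress path monotone in $v$ under a fixed seed,
and the whole report reproduces exactly — byte-identically — for identical
seed and inputs. Infeasible draws are excluded from statistics but counted.

## The synthetic generator

`generate_web()` emulates a plot-scale terrestrial arthropod community: six
guilds (plants, detritus, detritivores, herbivores, omnivores, predators),
lognormal body masses per consumer guild (log10 means 0–1.5 in mg — roughly
1 mg springtails to 30 mg carabids), Poisson abundances (≈8–80
individuals/m²), basal pools of 2×10⁴–5×10⁴ mg/m², 20 °C, and guild-rule
links (detritivores eat detritus; herbivores plants; omnivores plants,
detritus, herbivores, detritivores; predators the animal guilds) realized
with connection probability 0.6, every consumer guaranteed at least one
resource. Node biomass equals the sum of its drawn individual masses, so
biomass, abundance, and mean mass are exactly coherent. Guild adjacency is
acyclic, so every generated web is a DAG and energetically feasible by
construction — which is precisely what makes the generator a fair testbed
for the solver-vs-oracle equivalence and conservation properties.

What it deliberately does **not** emulate: empirical topology statistics
(connectance distributions, niche-model structure), intraguild predation
loops, cannibalism, spatial heterogeneity, or measurement error in biomass.
Tests passing on generated webs therefore demonstrate the *mathematics*
(balance, conservation, linearity, aggregation behaviour) on realistic
magnitudes, not that field data will be as well-behaved — real webs can be
energetically infeasible under bad inputs, which is exactly why infeasibility
is a loud error.

Problem sizes used throughout the tests and the acceptance script — webs of
roughly 6–20 nodes, 200 randomized webs for the oracle equivalence, 100 for
feasibility, 20–100 Monte-Carlo draws — are desk-scale on purpose: every
property asserted is size-free, and the chain fixture pins the arithmetic
exactly.

## Degenerate inputs and tie-breaks

* A consumer whose entire diet has zero biomass under passive preferences is
  a validation error (the normalization denominator would vanish).
* A web with no basal or no consumer node refuses to build; user-supplied
  basal flags must agree with the link structure (basal status is always
  derived, never trusted).
* Self-links with no explicit active weight refuse to build (see
  Preferences).
* `multifunctionality_index()` drops zero-variance processes with a warning;
  if nothing varies, every web scores 0 — identical communities are
  indistinguishable, not erroneous.
* The sequential solver refuses cycles and names the matrix solver; the
  cycle report lists the nodes on strongly connected components.

## Known limitations

* Steady-state only; no elemental (stoichiometric) fluxes; no link/diet
  inference from molecular or trait data.
* Consumer-level efficiencies apply one $e_c$ to a mixed diet literally —
  results differ from resource-level assignment whenever diets mix resource
  types, and the resource-level default is the recommended one.
* Bundled regression/efficiency coefficients are placeholders with
  provenance notes, not a curated trait database.
* Computed fluxes are comparative quantities: absolute values inherit the
  arbitrariness of what was sampled as the top of the web and the use of
  basal metabolic rates.
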