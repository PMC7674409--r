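---
title: "The hexcolony model: nutrient diffusion, trophic growth and lineage demixing on a hexagonal lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hexcolony model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexcolony)
```

## The system being modelled

`hexcolony` simulates surface-attached bacterial colonies expanding from a
mixed inoculum into fresh territory — a *range expansion*. The biological
template is a pair of isogenic denitrifying strains that either both run the
full nitrate reduction pathway (trophic **competition**), or split it into a
**producer** (nitrate to nitrite) and a **consumer** (nitrite onward),
cross-feeding the intermediate. Because nitrite is toxic at low pH, the
cross-feeding interaction can be tuned from **weak mutualism** (pH 7.5,
nitrite harmless, the dependency is unilateral) to **strong mutualism**
(pH 6.5, nitrite depresses the biomass yield of both partners, making the
dependency bilateral).

The simulator is individual-based on a hexagonal lattice: each occupied node
carries one *super-agent* (the many cells of one strain and one ancestral
lineage that fit into a 20 µm hexagon). The questions the model answers are
spatial-population-genetic ones: how do trophic dependencies shape sector
formation and intermixing at the expanding edge, how many founder lineages
survive to the periphery, and how unequal is reproductive success ("lucky"
lineages)?

## Model structure

Each macro time step (default 60 s) performs, in order:

1. **Boundary source.** Nitrate on the domain-rim nodes is reset to the
   reservoir concentration (1 mM), emulating nutrient supply from the
   surrounding agar.
2. **Diffusion.** Nitrate and nitrite diffuse by Fickian exchange along
   lattice bonds (see *Numerics* below). No flux crosses obstacle edges.
3. **Growth kinetics.** Each occupied node's specific growth rate is Monod
   in its substrate: µ = µ_max · C/(C + K), with nitrate for complete
   reducers and producers, nitrite for consumers. Under strong mutualism the
   *yield* (not the rate) is depressed by nitrite:
   Y = (Y_max − Y_min) · K_inh/(K_inh + C_NO2) + Y_min.
4. **Biomass update and consumption.** Explicit Euler growth
   m ← m(1 + µΔt); the matching molar uptake is µ·m·Δt/Y, clipped at the
   nutrient actually present in the node volume (biomass gain is scaled down
   with the realized uptake so stoichiometry is exact). Producers release
   one mole of nitrite per mole of nitrate consumed; consumers take their
   nitrite *before* same-step producer release is added, so a node can never
   consume nitrite produced in the same instant.
5. **Division and placement.** An agent at or above the critical division
   mass splits in half. The daughter goes to a uniformly random vacant
   neighbor if one exists; otherwise, if the shortest path through occupied
   nodes to the colony periphery is at most 5 edges (< 100 µm), the whole
   chain of cells along that path is shoved one node outward and the
   daughter takes the vacated origin; otherwise the daughter mass is added
   to a vertical "stacked" layer at the same node (pseudo-3D growth).
   Agents divide at most once per step, in uniformly shuffled order; an
   agent displaced by another's shove mid-sweep defers its own division to
   the next step.

Lineages are the bookkeeping core: every inoculated founder gets an
immutable id that travels with all its progeny, allowing peripheral-lineage
counts, interspecies boundary counts, consumer branch statistics,
lineage-loss percentages and the lucky-founder fraction to be computed
exactly at any time.

## Default parameters

| Parameter | Value | Units | Meaning |
|---|---|---|---|
| D (both solutes) | 1.7e-9 | m²/s | diffusion coefficient |
| µ_max | 5.4e-6 | 1/s | maximum specific growth rate |
| K_NO3 = K_NO2 | 0.04 | mM | Monod half-saturation |
| K_inh | 0.02 | mM | nitrite yield-inhibition constant |
| Y_max / Y_min | 0.06 / 0.006 | kgDW/mol | biomass yield range |
| boundary NO3 | 1 | mM | rim reservoir concentration |
| macro Δt / total | 60 / 259200 | s | time step and 72 h horizon |
| domain / inoculum | 5000 / 2000 | µm | full-scale geometry |
| hexagon side | 20 | µm | lattice resolution (pitch 34.64 µm) |
| division mass | 1e-10 | kg | super-agent critical mass (see below) |
| diffusion-layer depth | 1e-3 | m | slab depth setting node volume |

Two of these are genuinely free choices rather than measured quantities, and
both rescale the biomass–nutrient coupling:

* **Division mass (1e-10 kg).** A 20 µm hexagon holds on the order of 10⁵
  bacterial cells of ~3e-16 kg dry mass, giving ~1e-10 kg per super-agent.
  This knob controls the nutrient penetration depth
  λ ≈ √(D·C·Y·V_node/(µ_max·m)) and with it the expansion speed; the
  default makes a reduced-scale (1 mm) colony traverse a substantial part
  of its domain within the 72 h horizon, which is the behaviour the
  obstacle experiments require. Heavier super-agents thin the growth layer
  and freeze expansion entirely.
* **Depth (1 mm).** The pseudo-two-dimensional system needs a slab depth to
  convert concentrations (mol/m³) into node amounts; 1 mm represents the
  nutrient-bearing agar thickness. It only ever appears multiplied into the
  node volume, so halving the depth is equivalent to doubling every biomass.

## Numerics

**Bond conductance.** Flux between neighbors is D·A_bond/pitch with
A_bond = side × depth. On the triangular lattice of hexagon centers this
finite-volume choice reproduces the continuum diffusivity exactly
(1.5 · side · pitch = hexagon area), so no lattice calibration factor is
needed. The depth cancels between bond area and node volume.

**Two interchangeable schemes.** The reference scheme is explicit
forward-Euler pairwise flux, split into substeps chosen as
`ceiling(macro_dt / (0.5 × dt_stable))` with the positivity bound
dt_stable = 1/(max_degree × k). It conserves mass to floating-point
accuracy and is what the analytic fixtures exercise. Because the bound
forces ~680 substeps per 60 s macro step at the default parameters, the
simulation presets instead use an unconditionally stable backward-Euler
solver: the sparse system I + dt·L is Cholesky-factorized once per run and
reused every step. Backward Euler on a symmetric graph Laplacian conserves
total mass exactly, preserves non-negativity (M-matrix) and obeys the
discrete maximum principle; both schemes are checked against the closed-form
two-compartment solution and against each other in the test suite. The
first-order time error of either scheme is negligible relative to the
hour-scale evolution of the nutrient front.

**Degenerate inputs and tie-breaks.** Consumption is clipped at available
nutrient and the realized uptake propagated back into growth, so
concentrations never go negative and stoichiometric closure
(Δbiomass = Σ Y·mol) holds globally to 1e-6 relative, audited per run.
Shortest-path ties during shoving are broken by choosing uniformly among
equidistant periphery targets and then uniformly among shortest-path
predecessors while backtracking — a practical randomized tie-break over
(target, path) rather than a uniform draw over all distinct equal-length
paths. A shove whose path tip has no vacancy (impossible for a true
periphery node, but reachable through pathological occupancies) falls back
to stacking. Stacked biomass grows and consumes like the resident agent but
never divides laterally.

## Scenario presets and scales

`scenario_preset()` names the study's experiments:
`{competition, weak, strong} × {homogeneous, coarse, medium, fine,
stochastic}` plus `weak_noshove`, `weak_consumer_ring` and
`weak_producer_ring`. Structured habitats place solid 100 µm discs on a
square grid at 500/400/300 µm spacing; the stochastic variant draws
diameters from N(100, sd 20) µm (the "variance 20 µm" phrasing is read as a
standard deviation; a switch restores the literal reading). Obstacle discs
may overlap the domain rim and are clipped; the central inoculation disc is
always kept obstacle-free so the inoculum is placeable. Stochastic obstacle
fields are redrawn per replicate.

Three geometric scales are built in. `full` is the paper geometry (5 mm
domain, 2 mm inoculum, ~75,000 nodes). `reduced` (1 mm domain, 0.4 mm
inoculum, ~3,000 nodes, ~500 founders) is the desk scale used by the test
suite and the acceptance script; it keeps the full 72 h / 60 s temporal
conditions because µ_max·t is the dimensionless driver of every lineage
statistic — shrinking time rather than space would freeze the dynamics
(at 24 h, µ_max·t ≈ 0.5 means almost no divisions ever happen), whereas
shrinking space only reduces counting statistics. `mini` (0.4 mm, 12 h) is
a smoke-test scale. A reduced-scale replicate takes a few seconds on one
CPU; the statistics in the acceptance machinery use 6 replicates per
scenario at reduced scale.

## What the generator emulates — and what it does not

Replicates reproduce the study conditions: a 1:1 random strain assignment
over every node of the inoculation disc, initial masses uniform in 10–100%
of the division mass, stochasticity entering only through inoculation,
placement draws and shoving tie-breaks. Real colonies add much that the
model deliberately omits: cell geometry and mechanical force networks, EPS,
motility, death and lysis, mutation (cells are isogenic by construction),
pH dynamics beyond the binary toxicity switch, and any solute other than
nitrate and nitrite. Passing tests therefore demonstrate the internal
consistency of this idealized model, not quantitative prediction of plate
experiments.

One genuine tension deserves explicitness: with µ_max = 5.4e-6 1/s a
lineage's biomass can grow at most by e^(µ_max·t) ≈ 4 over 72 h, which
bounds how unequal reproductive success can become and how far a front can
advance (at most ~5 cells per ~36 h mass doubling). The strongly
concentrated published statistics (sub-percent lucky fractions, 99%
lineage loss, millimetre expansion) imply tens of generations and are not
reachable under these printed parameter values; the package reports what
the model as specified actually produces, and its qualitative orderings —
strong mutualism intermixes more and expands less, shoving enables consumer
branches, denser obstacles trap lineages — are the robust content at this
scale. Longer horizons or a larger µ_max restore many-generation dynamics
if a user wants them; both are plain config fields.

## Design choices where the design was open

* **Pitch convention.** Pointy-top axial coordinates; neighbor pitch =
  side·√3 ≈ 34.64 µm. The shoving rule "< 100 µm" is implemented as the
  cell-count reading (graph distance ≤ 5 edges), since 5 × pitch ≈ 173 µm:
  the two phrasings disagree and the discrete one is the implementable one.
* **Boundary nodes** are the rim nodes with incomplete neighbor rings; they
  carry the nitrate source. Nitrite is neither reset nor absorbed at the
  rim (closed for nitrite), since it originates only from metabolism.
* **Within-step ordering** (source → diffusion → kinetics on post-diffusion
  concentrations → biomass/reactions → division) fixes what the
  formulation leaves open; only "source before diffusion" is prescribed.
* **Growth-layer depth** for lineage-loss accounting defaults to 100 µm
  from the inoculum edge — the nitrate-penetration proxy matching the
  5-cell shoving radius — and is an explicit argument.
* **Encasement inoculations** overwrite the strain of the outermost
  occupied ring after random assignment, keeping founder ids.
* **Boundary counting** orders periphery agents by angle around the
  occupied-node centroid (radius breaks ties) and counts cyclic strain
  transitions; branch detection takes full connected components of
  consumer-occupied nodes (6-neighbor) that touch the periphery.
* **Replicate seeds** derive from the base seed by the fixed rule
  seed + i, recorded in each run's provenance together with a config hash.

## A worked mini example

```{r example, eval = FALSE}
cfg <- scenario_preset("weak", scale = "reduced", seed = 1)
run <- simulate_colony(cfg)
print(run)
run_statistics(run)

# replicate batch with summary table
rr <- run_replicates(scenario_preset("strong", scale = "reduced", seed = 1),
                     n = 6)
rr$summary
```

## Known limitations

Beyond the omissions listed above: the explicit scheme is impractically
slow at full scale (use the implicit default); metrics are recorded at a
configurable cadence, so sub-hour transients (e.g. the minutes-long
consumer nitrite lag) need `metrics_every = 1`; the angular boundary count
assumes a star-shaped colony outline and can miscount for extremely
invaginated fronts; and `lucky_fraction` is a percentage of founders, so
comparisons across geometries should account for founder number.
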