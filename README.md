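# hexcolony

Individual-based simulation of cross-feeding bacterial range expansion on a
hexagonal lattice.

Surface-attached colonies expanding from a mixed inoculum segregate
genetically: a few founder lineages ride the expanding front while most are
buried behind it. How strongly this happens depends on the trophic
relationship between the strains. `hexcolony` implements an agent-based
model of two denitrifying strains that either **compete** for nitrate (two
complete reducers), or cross-feed nitrite as **producer** (NO3⁻ → NO2⁻) and
**consumer** (NO2⁻ →), with nitrite toxicity switching the interaction from
weak (unilateral) to strong (bilateral) mutualism. It is aimed at
microbial ecologists studying spatial self-organization, genetic demixing
and "lucky lineage" effects during range expansion, including in structured
(porous) habitats.

## The model in brief

On a circular hexagonal lattice (side 20 µm), nitrate and nitrite obey a
diffusion–reaction balance along lattice bonds:

    dC/dt = D ∇²C  −  (µ/Y) m / V        (consumption; + production for NO2⁻)

with a constant 1 mM nitrate source on the rim. Each occupied node holds one
super-agent whose specific growth rate is Monod in its substrate,

    µ_i = µ_max · C_i / (C_i + K),       µ_max = 5.4e-6 s⁻¹, K = 0.04 mM,

and whose biomass follows m ← m(1 + µΔt) with molar uptake µ·m·Δt/Y. Under
strong mutualism (pH 6.5) nitrite depresses the yield of both strains:

    Y = (Y_max − Y_min) · K_inh/(K_inh + C_NO2) + Y_min.

Agents reaching the critical division mass split; daughters fill a vacant
neighbor, shove a chain of cells toward the periphery when it is fewer than
5 cells (< 100 µm) away, or stack vertically (pseudo-3D). Every founder
carries an immutable lineage id, from which the package computes peripheral
lineage counts, interspecies boundary counts, consumer branch statistics,
lineage-loss percentages and the *lucky fraction* — the smallest share of
founders holding more than half the final biomass.

See the methods vignette (`vignettes/colony-model.Rmd`) for the numerics,
parameter table and design choices.

## Worked example

A desk-scale weak-mutualism expansion (1 mm domain, 0.4 mm inoculum, 72 h of
simulated time; a few seconds on one CPU):

```r
library(hexcolony)

cfg <- scenario_preset("weak", scale = "reduced", seed = 1)
run <- simulate_colony(cfg)
print(run)
#> colony_run (weak_mutualism, seed 1): 72 steps recorded
#>   final: 941 occupied nodes, radius 592 um, biomass 8.02e-08 kg
#>   peripheral lineages: 32 + 49; boundaries: 46

str(run_statistics(run))
#> List of 11
#>  $ loss_growth_layer: num 64.5
#>  $ loss_all         : num 83.8
#>  $ lucky_fraction   : num 31.9
#>  $ boundaries       : int 46
#>  $ consumer_branches: int 13
#>  $ branch_ratio     : num 3.77
#>  $ periph_lineages_1: int 32
#>  $ periph_lineages_2: int 49
#>  $ total_biomass    : num 8.02e-08
#>  $ colony_radius    : num 592
#>  $ n_founders       : int 499
```

Reading the numbers: of the 499 inoculated founders, 83.8% left no
descendant on the final colony edge (64.5% even among founders that started
inside the actively growing 100 µm rim layer); the colony front advanced
from 400 to 592 µm; the periphery still carries 32 producer and 49 consumer
lineages separated by 46 strain boundaries; and 31.9% of founders account
for half of all biomass. Replicate batches with mean ± sd summaries come
from `run_replicates(cfg, n = 6)`, and `compare_runs()` applies the Welch
t-test between scenario batches.

A shell front end with `run`, `replicates`, `metrics` and `render`
subcommands is installed at `inst/cli/hexcolony`, e.g.

```sh
Rscript inst/cli/hexcolony run --preset weak --scale reduced --seed 1 --out out/
Rscript inst/cli/hexcolony replicates --preset competition_fine --scale reduced --n 6 --out out/
```

Runs write plain TSV tables (metrics time series, occupancy snapshots,
lineage tables); `render_snapshot()` rasterizes snapshots to PNG with
per-strain or per-lineage pseudo-colors.

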