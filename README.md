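# lucsim

Cellular-automata simulation of land use / land cover (LULC) change, policy
scenarios, and ecosystem service valuation.

`lucsim` is for landscape ecologists and regional planners who want to (i)
project a categorical land-cover map forward under Markov-chain demand, (ii)
allocate that demand spatially with competing cellular-automata (CA) engines,
(iii) constrain the allocation with policy zones (ecological protection red
lines, capital farmland), and (iv) translate the resulting maps into monetary
ecosystem service value (ESV) by benefit transfer. A synthetic landscape
generator with a known ground-truth Markov law makes the whole chain testable
without any external data.

## Models

**Demand.** A transition matrix `P` is estimated by row-normalising the
two-date cross-tabulation; class demand at horizon `n` steps is the
matrix-power projection `a' P^n`, rounded to whole cells by largest
remainder.

**Allocation.** Three engines place the demanded change on the map:

- *Markov CA* (`ca_markov_allocate`): deterministic ranked reallocation by
  `suitability × neighborhood density` in a 5 × 5 window.
- *FLUS-style* (`flus_allocate`): per-cell overall growth probability
  `OP[i,k] = P[i,k] · Inertia[k] · Ω[i,k] · R[i]`, where `P` comes from a
  single-hidden-layer ANN on driver surfaces, `Ω` is the neighborhood share
  of class `k`, `Inertia` adapts to the demand gap, and `R` is the binary
  restriction; contested cells are settled by roulette selection.
- *PLUS-style* (`plus_allocate`): expansion probabilities from per-class
  random forests trained on newly-converted cells (land expansion analysis
  strategy), plus multi-type random patch seeding under a decreasing
  threshold `τ = δ^l · r1` and a binary allowed-transition matrix `TM`.

**Validation.** Simulated maps are compared to observations with the
confusion matrix, overall accuracy `P0` and Cohen's kappa
`(P0 − Pc)/(1 − Pc)`, banded at 0.75/0.4.

**Valuation.** Per-service ESV is the benefit transfer
`value_s = Σ_j area_j[ha] · V[s,j] / 10^6` (10^6 yuan · yr⁻¹), using a
packaged nine-service × six-class regional coefficient table whose built-up
column is zero.

**Pattern.** Landscape-level Shannon diversity (SHDI), evenness (SHEI) and
contagion (CONTAG, 4-neighbour, double-count) summarise fragmentation across
scenarios.

## Worked example

```r
library(lucsim)

scene <- make_scene(rows = 120, cols = 120, seed = 2)   # synthetic test scene
run <- run_pipeline(scene$t0, scene$t1, scene$t2, scene$drivers,
                    scenario_config("S4", engine = "plus",
                                    horizon_steps = 3, seed = 3),
                    masks = scene$masks)
run
#> <pipeline_run> scenario S4, engine plus
#>   validation kappa: 0.9195 (high)
#>   horizon total ESV: 120.42 x10^6 yuan/yr (change -4.29)

round(run$metrics, 4)
#>           shdi   shei  contag
#> horizon 1.4127 0.7884 32.8068
```

The run calibrates a Markov matrix on the first date pair, simulates the
third date and validates it (kappa 0.92: the engine recovers the held-out
map well), re-calibrates, projects demand three steps ahead, allocates it
with the patch-seeding engine while freezing the union of the two policy
masks (scenario S4), and values the horizon map: total ESV falls by
4.29 × 10^6 yuan/yr because grassland and water lose cells to farmland and
built-up land.

Valuing a published area table directly:

```r
co <- load_coefficients()
ar <- tongliao_areas()
esv_from_areas(setNames(ar[, "y2020"], rownames(ar)), co)
#> <esv_snapshot> 10^6 yuan/yr
#>   Food production 2547.66, ..., Recreation and culture 3420.83
#> Total: 51620.62
```

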