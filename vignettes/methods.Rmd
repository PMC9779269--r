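---
title: "Methods: CA land-use simulation and ecosystem service valuation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CA land-use simulation and ecosystem service valuation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lucsim)
```

`lucsim` chains five stages: Markov demand projection, spatial allocation by
one of three cellular-automata (CA) engines, kappa validation against a
held-out date, policy-scenario restriction, and benefit-transfer valuation.
This vignette explains each model, the parameters that matter, the numerical
choices, and what the synthetic test conditions do and do not demonstrate.

## The grid model

A landscape is a `lulc_raster`: an integer matrix of class codes with a
nodata code, a cell size in metres (default 100 m, so one cell is 1 ha), a
legend, and a lower-left georeference. Row 1 is the northern row; all
internal indexing is row-major from the upper-left. Alignment between
rasters is checked to within 1e-6 of a cell and a mismatch is an error —
never an implicit resample, because resampling belongs upstream of analysis.
Any cell that is nodata in any input of a multi-raster operation is excluded
from that operation.

## Demand: the Markov chain

`estimate_transition_matrix()` row-normalises the two-date cross-tabulation.
A class absent at the first date is unobservable and receives an identity
row with a warning rather than NaN. Demand at the horizon is
`areas %*% probs^n` with whole matrix applications only: a 5-year matrix
carried 15 years forward means `n = 3`. Fractional matrix powers are
deliberately unsupported — roots of stochastic matrices need not exist, be
unique, or be stochastic. Demand is converted to whole cells by
largest-remainder rounding so the class total equals the valid-cell count
exactly; this matters because the diversity metrics compare scenarios by
composition and should see *identical* compositions when demand is shared.

## Allocation engines

All three engines move cells from over-supplied to under-supplied classes
until the composition matches demand (default tolerance: 0 cells), freezing
any cell where the binary restriction grid is 0.

**Markov CA.** Candidate cells are ranked by
`suitability × (neighborhood share + 0.01)`; ties are broken by a seeded
uniform jitter so runs are reproducible. The 0.01 floor keeps the ranking
meaningful when a growing class has no patches yet (a pure cold start would
otherwise rank by jitter alone). The default suitability stack is the
later-date class indicator smoothed by the 5 × 5 mean filter — a transparent
analogue of suitability maps produced by desktop GIS workflows; callers can
supply their own stack. A completion sweep at the end of each cycle re-ranks
the full remaining pool for any class whose trimmed candidate list ran dry,
so feasible demand is always met exactly.

**FLUS-style.** The overall growth probability is
`OP[i,k] = P[i,k] · Inertia[k] · Ω[i,k] · R[i]`.

- `P` comes from a single-hidden-layer neural network (sigmoid hidden units,
  softmax output; default 12 hidden units, sized for a driver stack of
  around a dozen layers) trained on sampled cells with standardized drivers.
  The per-cell outputs are normalised to a probability simplex so the
  roulette competition compares like with like across classes; an
  unnormalised sum of sigmoid outputs would make the competition
  scale-dependent.
- `Ω[i,k]` is the share of the n × n window (default n = 3, configurable;
  the Markov CA uses the classic 5) occupied by class k, centre excluded —
  the `n² − 1` denominator implies the centre is not its own neighbour.
  Edge cells use shrunken windows with matching denominators rather than
  padding, so `Ω` stays in `[0, w_k]` everywhere.
- `Inertia` starts at 1 per class and follows the three-branch gap rule:
  unchanged while the absolute demand gap is not growing, scaled by
  `D2/D1` when a negative gap (overshoot) worsens, and by `D1/D2` when a
  positive gap (shortfall) worsens. It is applied only to classes still
  below demand; shrinking classes release cells by losing competitions.
- Each iteration updates a seeded random batch (default 50%) of the cells in
  over-supplied classes; the roulette draw is restricted to classes still
  short of demand, which is what makes convergence fast — cells whose draw
  fails keep their class for that round.

If no change is accepted for several consecutive iterations (default 5), the
engine falls back to deterministic ranked assignment by raw potential. This
guarantees that feasible demand converges; the convergence log (per-iteration
gaps, counts, decay state) is attached to every result for audit.

**PLUS-style.** Three additions to the roulette engine: (i) a candidate cell
becomes a fresh patch seed with small probability (default 0.02), waiving
the neighborhood term so growth can start away from existing patches;
(ii) a candidate conversion into class c is accepted only when its expansion
probability exceeds the decreasing threshold `τ = δ^l · r1`, with `δ = 0.9`,
`r1` a half-normal draw truncated to (0, 1], and `l` incrementing whenever an
iteration narrows the total absolute demand gap by less than `Step` (default
1% of the initial gap) — so acceptance starts strict and loosens until
feasible demand completes; (iii) a binary transition matrix `TM` forbids
specific class-to-class conversions outright (its diagonal must be 1). The
per-class gap `G_c` in the decay rule is interpreted as demand minus current
count, the same sign convention used everywhere else. The expansion
probabilities come from per-class binary random forests (default 100 trees,
`√n_features` per split, impurity importances) trained on cells that newly
converted into the class between the calibration dates, against an equal
number of sampled non-converted cells; classes with fewer than 10 expansion
cells get a flat 0.5 surface with a warning. The surfaces are deliberately
*not* normalised across classes — each is a per-class expansion propensity,
not a membership probability.

## Validation

`agreement()` computes the confusion matrix over jointly valid cells,
overall accuracy `P0`, and Cohen's kappa with chance agreement taken from
the marginals and ideal accuracy 1. Band thresholds are the conventional
0.75 (high) and 0.4 (general). We use Cohen's convention deliberately: it is
the definition under which those thresholds were derived, and it makes kappa
exactly 0 for a constant map against any marginal, and invariant to
simultaneous class relabelling (both property-tested).

## Scenarios

`build_restriction()` maps policy zones to the binary restriction: S1
(inertial) freezes nothing, S2 freezes the ecological-protection red line
(EPRL), S3 freezes capital farmland (CF), S4 their union. Demand is shared
across scenarios — only the restriction differs — so SHDI/SHEI, which depend
only on composition, are identical across scenarios whenever all engines
converge exactly; this is why the exact-demand default matters. The mask
assignment is explicit in the configuration, so either naming convention for
the single-policy scenarios can be run without code changes.

## Valuation

`esv_from_areas()` implements benefit transfer:
`value_s = Σ_j area_j[km²] · 100 · V[s,j] / 10⁶`, in 10⁶ yuan · yr⁻¹. The
single unit conversion (100 ha/km²) is centralized in one constant and
covered by a conservation test: summing the per-cell surface
(`esv_per_cell()`, yuan per cell) over the grid equals the aggregate total
to 1e-6 relative. The packaged coefficient table is a nine-service ×
six-class regional revision of the Chinese equivalent-factor tables with the
built-up column set to zero (construction land is valued as a loss of
ecosystem services); the table ships as data because its derivation (a
provincial weighted-average revision) is upstream of this package's scope.

## Landscape metrics

SHDI is `-Σ p ln p` over classes present; SHEI divides by `ln(K)` of the
legend, so it is 1 only when every legend class is equally abundant. CONTAG
follows the FRAGSTATS landscape-level definition with 4-neighbour adjacency
and like-adjacencies double-counted, with `m` = classes present. One
degenerate case is worth knowing: a single-cell two-class checkerboard has
pair entropy exactly `ln 2`, giving CONTAG exactly 50 — *above* a two-block
split (≈ 46.7) — because perfect alternation is a perfectly ordered adjacency
distribution, not a maximally mixed one. Any patch-level checkerboard (block
size ≥ 2) scores near 0 and sits below aggregated maps, which is the
fragmentation ordering the metric is used for. Both values are frozen in the
test suite from the closed-form adjacency counts.

## Ordinary kriging

Driver surfaces can be interpolated from point observations with ordinary
kriging: spherical/exponential/Gaussian variograms, fitted by weighted least
squares (pair-count weights) on the binned empirical semivariogram; the
constrained weight system is solved directly, so weights sum to 1 at every
node and the surface interpolates the data exactly when the nugget is 0.
Duplicate coordinates are merged by mean (they make the system singular).
Accuracy is reported as leave-one-out ME and RMSE. Universal/co-kriging and
anisotropy are out of scope.

## The synthetic scene: what it shows and what it does not

`make_scene()` generates the study conditions used throughout the tests: a
6-class landscape (30/8/43/2/3/14% — grassland-dominated with farmland
second, the composition profile of a semi-arid agro-pastoral region)
produced by thresholding a smoothed Gaussian field at the proportion
quantiles; two later dates evolved by a known, strongly diagonal transition
matrix (diagonals 0.94–0.995, main exchanges among farmland, grassland and
unused land, steady built-up growth — per-class totals change by only a few
percent per step, the slow-dynamics regime); five driver layers built as
`signal × class-mean surface + (1 − signal) × smooth noise` (default signal
0.8); and contiguous policy masks (default 15% each) that preferentially
overlap grassland/forest (EPRL) and farmland (CF). Everything is
deterministic under its seed.

These conditions support parameter-recovery tests (the estimated matrix
approaches the ground truth within 0.02 max-abs at 500 × 500), potential
sanity checks (ANN accuracy > 0.95 on fully separable drivers, chance-level
on noise; random-forest importance > 0.8 on a single causal driver), and
demand/restriction guarantees. They do **not** emulate frontier-driven
change: the ground-truth process flips cells independently given class, so
real-world spatial concentration of change along patch frontiers is absent.
One visible consequence: freezing the EPRL zone (which covers the interiors
of the largest grassland patches) suppresses scattered conversions inside
big patches and can *raise* horizon contagion slightly relative to the
unrestricted scenario, while the farmland-covering CF mask shows the
expected fragmentation direction. Passing tests on this scene therefore
demonstrate mechanical correctness of the engines, not that policy masks
always fragment growth on real landscapes.

## Problem sizes and runtime choices

The test suite runs the standard scene at 300 × 300 (engine, restriction and
scenario checks; ~2 s per patch-seeding allocation), 500 × 500 for Markov
recovery, 120–150 squares for model-fitting checks, and 20 seeds for the
stochastic contagion comparison — sizes chosen so the full chain, including
two random-forest trainings per pipeline run, stays comfortable on a single
CPU while keeping binomial/recovery tolerances tight.

## Known limitations

- The engines guarantee composition; they do not model patch geometry
  explicitly, so patch-level metrics are out of scope.
- Restriction is binary; graded conversion costs are not supported.
- Demand feasibility under heavy restriction (a class demanded below its
  frozen count) is detected and warned, not resolved.
- The CA-Markov suitability analogue is declared, not inferred from any
  external software's behaviour; users reproducing a desktop-GIS workflow
  should supply their own suitability stack.
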