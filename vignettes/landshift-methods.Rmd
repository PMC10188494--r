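---
title: "landshift: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{landshift: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landshift)
```

This vignette documents the science implemented in `landshift`: the
downscaling allocator, the two NCP indicators, the scenario machinery, the
synthetic-data generator that drives them, and the numerical and design
choices made where the underlying methods leave room.

## 1. The two-level grid

Everything lives on a fine pixel grid (`grid_spec`) tiled exactly by coarse
cells of `coarse_factor` pixels per side. The reference configuration mirrors
the resolutions the approach is designed for — 0.5° coarse cells downscaled
to ~300 m (10 arc-second) pixels, a factor of 180 — but the factor is fully
configurable and the test and example configurations use factors of 10–20 so
that whole pipelines run in seconds. Row 0 is the northernmost row; coarse
cell (I, J) owns fine rows `[I·F, (I+1)·F)`.

Pixel areas come from a `cell_area_model`: *uniform* mode (every pixel the
same area in ha) is the default for experiments because it removes latitude
effects from conservation arithmetic; *spherical* mode computes true
lon/lat-quad areas, `R²·Δλ·(sin φ_top − sin φ_bot)`. All areas are hectares;
soil-loss totals convert Mg → Pg as 1 Pg = 10⁹ Mg.

## 2. Downscaling by suitability-ranked allocation

Coarse, per-cell, per-class area changes are allocated to fine pixels in
three stages.

**Suitability.** Per class *c* the overall score is the sum of

* an *adjacency surface* `A_c = w_near·(K_σnear ⊛ 1_c) + w_far·(K_σfar ⊛ 1_c)`,
  where the kernels are isotropic truncated Gaussians (radius 3σ, unit mass,
  boundary-renormalised over in-map mass). Two scales capture both distance
  to existing class pixels and their agglomeration: the near kernel rewards
  immediate adjacency (field edges), the far kernel rewards being inside a
  larger cluster. Defaults `σ_near = 2`, `σ_far = 8` pixels,
  `w_near = 1`, `w_far = 0.3`.
* a *physical suitability* `S_c = a_soc·soc01 + b_tri·(1 − tri01)` from
  min–max-normalised soil organic carbon and terrain roughness (TRI =
  root-sum-of-squares of elevation differences to the 8 neighbours). A
  constant input normalises to 0.5 by declared convention, so degenerate
  covariates contribute a neutral, not extreme, score.

**Eligibility.** A 7 × 7 allowed-transition matrix (water and urban are
terminal; barren is never created; defaults in `transition_defaults()`), and
protection rules: protected pixels never lose natural classes (forest,
non-forest vegetation, grassland) and never gain cropland or urban.

**Allocation.** Per coarse cell, ha changes become pixel counts by
largest-remainder rounding (counts sum to zero per cell). Iteratively, the
gaining class with the largest remaining demand (ties: smallest class id)
claims the eligible pixel with the highest score among pixels of classes
with remaining loss demand (ties: first in row-major order). This "loser
determined by the winner's best pixel" rule is one consistent reading of how
contraction should be ordered when several losing classes coexist; any total
order would do, and these tie-breaks are frozen so the allocator is fully
deterministic. Ranking is per coarse cell, matching the cell-level
accounting of the coarse model — there is no cross-cell spillover. On
success the aggregated output equals the rounded targets exactly (asserted
internally); infeasibility raises an error carrying per-cell deficits rather
than ever returning a silent partial allocation.

**Calibration.** `calibrate_allocation()` is an explicit grid search: each
candidate parameter set re-runs the allocator over the holdout change
series, starting from the last observed fit-period map, and is scored by the
changed-pixel mismatch loss
`|pred ≠ obs| / |{pred ≠ base} ∪ {obs ≠ base}|` (0 when nothing changed).
The loss surface is piecewise constant in the parameters, so continuous
optimisation would gain nothing over a well-chosen grid; ties break to the
first candidate, keeping the procedure deterministic. When the histories are
generated by a parameter set contained in the grid, that set achieves loss 0
and is recovered.

## 3. Pollination sufficiency

For each cropland pixel, *p* is the proportion of habitat pixels among all
in-map pixels whose centres lie within the foraging radius (default 2000 m)
of the focal centre, and `s = min(p/τ, 1)` with τ = 0.30. Design choices:

* **Window denominator.** All in-map window pixels count; water and urban
  are non-habitat rather than excluded. The alternative (excluding them)
  would make a cropland pixel beside a lake score higher; both readings are
  defensible, this one is configurable via the habitat set.
* **Closure at the threshold.** `p = τ` maps to `s = 1` — the ramp is
  defined on [0, τ) and saturation on [τ, 1]. The verbal definitions
  ("> 30 %" for sufficiency, "between 0 and 30 %" for the ramp) leave the
  boundary point ambiguous; closing at τ makes `s = 1 ⇔ p ≥ τ` exact.
* **Metric.** Circle membership uses pixel-centre distance in a uniform
  planar metric (metres per pixel from `pixel_size_m()`, 111,320 m per
  degree, or an explicit override). Sufficient at desk scale; no geodesic
  windows.
* **Classes.** Low/moderate/high bounds are exact thirds (1/3, 2/3),
  treating the printed 0.33/0.67 as rounded display; intervals are
  left-closed with the top class closed at 1. Summaries report class areas
  for all cropland and restricted to *historic* cropland (pixels that were
  cropland at the baseline year), separating in-situ change from frontier
  expansion, plus the class-transition matrix.
* The grassland-exclusion robustness variant is the same computation with
  `habitat_classes = c("forest", "non_forest_vegetation")`; since the
  habitat set shrinks, `p_variant ≤ p_default` pixel-wise.

## 4. Soil loss

`A = R · K · LS · C` in Mg ha⁻¹ yr⁻¹, support-practice factor fixed at 1
(management held constant across scenarios).

* **K** uses the EPIC-type algebraic approximation from sand/silt/clay/
  organic-carbon percentages (formula in `?k_from_soil`), consistent with
  the large-scale RUSLE modelling lineage this module follows; it is the
  pinned, tested interpretation of "algebraic approximation".
* **LS** follows the two-dimensional contributing-area formulation: Horn
  8-neighbour slope, deterministic D8 flow accumulation (steepest descent,
  ties to the first neighbour in the fixed scan order), exponent
  `m = β/(1+β)` with `β = (sin θ/0.0896)/(3 sin θ^0.8 + 0.56)`, the
  contributing-area L expression with aspect factor `x = |sin α|+|cos α|`,
  and the two-branch S (`tan θ < 0.09` implements the 9 % threshold). The
  contributing area is capped (default 1 km²) to avoid channelised-flow
  artefacts, and LS itself can be capped. A flat DEM yields LS = 0.03
  exactly (m = 0, L = 1, S = 0.03), which the tests pin at 10⁻⁹.
* **C** on cropland is the per-coarse-cell area-weighted mean over 20 crop
  groups, disaggregated uniformly to the cell's cropland pixels; elsewhere
  `C = C_bare·(1−f) + C_full·f` with f = tree cover on forest and annual
  vegetation cover on grassland / non-forest vegetation. The default C
  table (`c_factor_defaults()`) ships literature-representative placeholder
  values spanning the usual ranges; it is an editable configuration
  surface, not reference data.
* **Aggregation** reports totals per region for all land, cropland, and
  historic cropland, and a seven-class erosion raster with configurable
  breakpoints (defaults 0.5, 1, 2, 5, 10, 20 Mg ha⁻¹ yr⁻¹ — the European
  soil-classification tradition names seven classes but not unique numbers,
  so these are explicit configuration).

## 5. Scenarios

`scenario_preset()` encodes the four archetypes (BAU none; PROTECT
conservation; COACTION + climate; MULTI + landscape policy):

* **Carbon price** `p(t) = 109.8·1.05^(t−2025)` USD/tCO₂, reaching 371.8 in
  2050; undefined before 2025 by construction. It parameterises the climate
  policy's strength; the translation into conversion costs is economic
  modelling outside this package, represented by the expansion damping and
  reforestation demand below.
* **Protection** phases the conservation template in linearly 2020 → 2030
  ("gradually" is not otherwise specified); cells are protected in a seeded
  deterministic order, so fraction f protects the first ⌈f·n⌉ template
  cells and protected sets are nested over time. Primary forest reaches
  full protection by 2025; the synthetic legend carries a single forest
  class, so the schedule exposes the flag but the generator applies the
  template schedule only.
* **Landscape cap** 0.90 at 2025 falling linearly to 0.80 at 2030, constant
  after; before 2025 only the universal 90 % availability constraint
  applies. Cap enforcement relocates excess cropland: removals are
  `ceiling(excess)` in whole hectares (guaranteeing the cap), receipts go
  to unprotected under-cap cells proportionally to slack with
  capacity-capped largest-remainder rounding, so removed and received
  totals balance exactly and global cropland is conserved to the hectare.
  Relocation proportional-to-slack is a deterministic, order-free stand-in
  for the cost-optimised relocation of a full economic model; removed
  cropland restores to non-forest vegetation by default (semi-natural
  habitat restoration), configurable.

## 6. The synthetic-data generator

The generator produces the study conditions for all tests and examples:

* **Landscape**: white noise smoothed at `autocorrelation_length` (default
  6 pixels ≈ 1.8 km at 300 m pixels, a plausible farmland-mosaic grain) and
  thresholded at class-mix quantiles, so realised fractions match the mix to
  one pixel. The default mix (cropland 0.35, forest 0.25, grassland 0.15,
  non-forest vegetation 0.10, water 0.06, barren 0.05, urban 0.04) gives a
  mixed agricultural landscape with ~50 % semi-natural habitat; the
  threshold order places cropland between grassland and urban along the
  field gradient, giving realistic adjacency structure.
* **Covariates**: smooth log-normal/logistic transforms of Gaussian random
  fields for SOC, DEM, erosivity, texture (softmax of three fields, summing
  to 100 %), covers; Dirichlet crop shares over 20 groups; potential
  cropland 55–90 % of cell area; a contiguous conservation template
  (default 25 % of cells — of the order of the global conservation-priority
  templates the scenarios emulate); a boreal band (northernmost 15 % of
  coarse rows); potential-vegetation carbon density spanning 5–125 t C ha⁻¹
  so the 20 t C ha⁻¹ reforestation eligibility threshold bites.
* **Demand**: cropland grows by `cropland_expansion_rate` (default 9 % per
  5-year step, i.e. ~83 % cumulative growth over 2015–2050 if unconstrained
  — a deliberately strong frontier-expansion baseline) at the expense of
  the cell's natural classes; under climate policy the rate is multiplied
  by 0.2 and a reforestation demand (default 0.4 % of domain area per
  step) is placed on eligible cells, sourced from grassland and non-forest
  vegetation. These magnitudes are free configuration: in the full modelling
  chain they emerge from an economic model that is out of scope here, so
  they are chosen once as a plausible contrast and not tuned.
* **Feasibility by construction**: every generated loss keeps a four-pixel
  per-class margin below the class's stock, absorbing largest-remainder
  rounding drift across steps, so generated change series are always
  allocatable.

What the generator does *not* emulate: real-world class geometry (roads,
rivers, field shapes), covariate cross-correlations (e.g. SOC–climate),
demand heterogeneity between regions, price dynamics, or climate impacts.
Passing tests therefore demonstrate the correctness and the qualitative
scenario behaviour of the machinery, not calibrated real-world magnitudes —
global headline numbers require the full global model chain and data.

## 7. Numerical conventions and degenerate inputs

* Conservation checks use exact pixel-count equality after rounding;
  area-level checks use 10⁻⁶ relative tolerance.
* Ties everywhere break by fixed total orders (class id, row-major pixel
  order, first candidate), making every routine bit-reproducible; all
  randomness flows from explicit integer seeds (`withr::with_seed`), never
  global state.
* Constant covariates normalise to 0.5; all-nodata DEMs, empty candidate
  grids, sub-pixel pollination radii, zero silt+clay, and cropland on
  zero-potential cells raise immediate errors.
* Raster I/O uses ESRI ASCII grid with a YAML legend sidecar — a plain-text
  interchange format that carries the georeferencing the package needs.

## 8. Problem sizes

The shipped tests and the acceptance script run on 40–120 pixel grids with
coarse factors 10–20 and 2–7 time steps, sizes chosen so the full suite
exercises every code path, including 50-scenario allocation sweeps and
10-seed scenario contrasts, in about a minute of CPU. All algorithms are
O(pixels × kernel) or O(pixels log pixels) and scale to larger domains
linearly in memory.

## 9. Known limitations

* Allocation is strictly per coarse cell; demand cannot spill into a
  neighbouring cell even when locally infeasible (the error reports the
  deficit instead).
* The pollination model has no species-specific foraging kernels,
  floral-resource weighting or yield feedback; the soil module covers sheet
  and rill water erosion only (no wind, tillage, gully or landslide
  processes), with erosivity held constant over time.
* The carbon price influences the simulation only through the damped
  expansion rate and the reforestation demand; there is no cost
  optimisation, trade, or food-demand response.
* Spherical-area mode treats pixels as lon/lat quads on a sphere; no datum
  or projection handling.
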