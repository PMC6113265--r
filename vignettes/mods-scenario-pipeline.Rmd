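---
title: "Scenario analysis of land-use change and ecosystem-service interactions in mountain-oasis-desert landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scenario analysis of land-use change and ecosystem-service interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modses)
```

## The problem the package addresses

Arid Central-Asian prefectures share a three-belt structure — high mountains,
an irrigated riverine oasis corridor, and surrounding desert (the
mountain-oasis-desert system, MODS). Land-use policy in such regions moves
land between six cover classes (cropland, forest, grassland, water, built-up,
bare), and each move shifts a bundle of ecosystem services at once: water
yield (WY), crop production (CP), soil conservation (SC), sand fixation (SF),
carbon sequestration (CS) and landscape aesthetic value (AV). The package
implements the full chain of a scenario analysis of those shifts:

1. **Demand**: a Markov chain projects per-class land demand, with policy
   scenarios expressed as multiplicative modifiers on specific transition
   probabilities.
2. **Allocation**: a FLUS-style cellular automaton places the demand in
   space, driven by a neural-network suitability surface, neighborhood
   enrichment, conversion-cost gates and self-adaptive inertia.
3. **Quantification**: six per-pixel service models.
4. **Interactions**: regional min-max-normalized trend series (flower-diagram
   data) and a per-pixel six-digit overlay code that locates multi-service
   trade-offs and synergies, filtered by area and attributed to the land-use
   transitions beneath them.

Because the package is exercised entirely on synthetic landscapes, every
stage is testable without geodata; the synthetic generator is itself a
first-class, tested module.

## The synthetic landscape

`generate_landscape()` emulates the structural features the downstream stages
rely on, not any real geography:

* a north-to-south descending DEM (default 3500 m down to 400 m) with
  spatially correlated relief;
* precipitation increasing with altitude (`base + lapse * elevation` plus a
  correlated noise field; defaults 120 mm/a at the lowest elevation and
  0.05 mm per metre, giving the ~120-280 mm/a span typical of such regions);
* a meandering river running south and an oasis corridor defined as
  low-elevation land within a buffer of it; zones are elevation terciles
  (mountain = top band, oasis = low band near the river, desert = the rest);
* land cover placed by zone-conditional priors (cropland and built-up near
  the river in the oasis, forest in the mountains, bare land in the desert)
  and then filled greedily to hit the target composition exactly, so the
  realized class shares differ from the requested ones only by integer
  rounding. The default composition is the 2015 MODS mix: 34.9% grassland,
  7.3% forest, 3.6% cropland, 52.3% bare, and 1.9% water plus built-up
  (split 1.2% / 0.7%);
* soil texture/organic matter and RWEQ weather/crust/roughness factors that
  vary by zone with correlated noise.

All randomness flows through one seeded generator per call
(`with_local_seed()`), so identical configurations reproduce bit-identical
bundles and the global RNG state is never touched.

What the generator does **not** emulate: a real river network and its
irrigation system, inter-annual climate variability (drivers are multi-year
means, as in annual-scale service assessments), spatially autocorrelated
*change* processes (the calibration-period dynamic draws each pixel's
transition independently), and any real meteorological record. Passing tests
therefore demonstrate the correctness of the algorithms and the internal
consistency of the pipeline — not calibration to any real region.

## Land-use change model

**Transition estimation.** `estimate_transition_matrix()` cross-tabulates two
dated maps; rows of classes absent at the first date become identity rows
rather than invented dynamics.

**Scenario modifiers.** The three built-in scenarios follow the common
policy-storyline convention: business-as-usual (no modifiers), economic
development (conversions of forest/grassland/water/bare into cropland +50%,
of cropland/forest/grassland/bare into built-up +200%), ecological
conservation (forest/grassland/water into cropland or built-up −100%, bare
into cropland/built-up −50%, cropland into forest/grassland/water +80%).
`apply_scenario_modifiers()` multiplies the targeted off-diagonal entries by
`1 + change` and lets the **diagonal absorb the residual**, which preserves
the stated relative changes exactly. Only when the diagonal would go negative
are the off-diagonal entries rescaled proportionally (diagonal pinned at 0).
The alternative — rescaling the whole row — would distort the advertised
percentages on the targeted conversions, which is why it is only the
fallback.

**Projection stepping.** The calibration matrix covers a 15-year period but
projections are reported every 5 years. `step_split_matrix()` computes the
principal matrix root through the eigendecomposition (`Q^3 ≈ P`), reporting
the achieved Frobenius error and falling back to clip-and-renormalize
regularization when no clean stochastic root exists (e.g. periodic or
non-diagonally-dominant matrices). Five-year stepping is a modelling choice:
annual-scale roots exist equally, but 5-year steps match the reporting
horizon and keep the CA's per-step demand moves well above rounding noise.

**Suitability.** `train_suitability()` is a single-hidden-layer softmax
network (via `nnet`): hidden size `2 * n_factors`, min-max factor
normalization, a uniform 5% pixel sample topped up to at least 50 pixels per
present class, weight decay `1e-4`. None of these values is canonical in the
literature; they are defaults chosen so training is fast and reproducible on
desk-scale grids, and all are arguments.

**Cellular automaton.** `ca_allocate()` combines, per candidate pixel and
target class: suitability × (ε + neighborhood weight × share of the class in
the 3×3 Moore window) × self-adaptive inertia × conversion-cost gate, and
draws the next class by a seeded roulette wheel. Two hard gates make the
allocation monotone and safe: pixels may only leave classes above their
demand, and only enter classes below it, so cost-forbidden transitions never
occur, total pixel count is conserved, and overshoot is impossible. The
inertia coefficient multiplies by `1 ± inertia_step` (default 0.1) each
iteration a class lags/overshoots demand, bounded to `[1e-8, 1e8]`: wide
bounds are deliberate, since low-suitability ground must eventually accept
conversions when demand persists (the small ε = 1e-4 in the neighborhood term
similarly allows new patches to nucleate away from existing ones). The exact
inertia constants are ours and configurable; published FLUS-style automata
state the piecewise self-adaptive idea but not portable constants.

**Validation.** `roc_auc()` is the rank-based (Mann-Whitney) AUC per class
with midrank ties; `kappa_statistic()` is Cohen's kappa from the confusion
matrix, defined as 1 in the degenerate all-agree case (`p_e = 1`). Both are
invariant to consistent relabeling.

## Service models

* **WY** (mm/a): water balance `Y = (1 − AET/P) · P`. The AET sub-model is
  the Budyko-Zhang curve `AET/P = (1 + wφ)/(1 + wφ + 1/φ)` with aridity
  `φ = Kc·ET0/P` and per-class `Kc` and plant-available-water `w`; it keeps
  `AET/P` in `[0, 1)` for all inputs, hence `0 ≤ Y ≤ P` everywhere. A
  precomputed AET raster can bypass the curve. Zero-precipitation pixels
  yield 0 and are counted in a flag attribute rather than producing NaN.
* **CP**: `CP = P_v · I_zrd` on cropland, 0 elsewhere. `P_v` is the
  Miami-type climatic productivity `min(3000/(1+e^{1.315−0.119T}),
  3000(1−e^{−0.000664P}))` — the standard stand-in behind farmland-grading
  indices; `I_zrd ∈ [0, 1]` is the land-quality index raster.
* **SC** (t km⁻² a⁻¹): USLE, `A = R·K·L·S·C·P_s`, potential `A_r = R·K·L·S`,
  conservation `A_c = A_r − A ≥ 0` (guaranteed by `C·P_s ≤ 1`). Shipped
  sub-factor defaults (Wischmeier-type annual `R` from precipitation, EPIC
  `K` from texture and organic matter, standard `LS` from DEM slope) exist so
  the pipeline runs end-to-end; all four factors accept precomputed rasters.
* **SF** (t km⁻² a⁻¹): RWEQ. `Qmax = 109.8·Π`, `S = 105.71·Π^{−0.3711}`
  with `Π = WF·EF·SCF·Ka·C`, and transported mass
  `Q(x) = (2x/S²)·Qmax·e^{−(x/S)²}`. The distance symbol in the transport
  equation is read as the downwind distance x (one `field_length` parameter,
  default 50 m). Sand fixation is `ΔQ = Q0 − Qv`, where `Q0` forces the
  vegetation factor to 1 (bare potential) while the crust and roughness
  factors keep their mapped values — removing vegetation should not also
  remove the crust. `ΔQ ≥ 0` whenever `C ≤ 1`. Note `Q(x)` at fixed x is not
  monotone in `Π` over all magnitudes (the shrinking critical length
  eventually starves transport at the measurement distance); with realistic
  sub-unity cofactors the sand-fixation response to the weather factor is
  monotone, and the tests pin exactly that regime.
* **CS**: per-pixel density is the sum of the four pools (above-ground,
  below-ground, soil, dead organic) of the pixel's class (kg C m⁻²); the
  regional total multiplies by pixel area. Linear in both the density table
  and class areas.
* **AV**: each pixel carries its class's mean survey score (0-5 scale);
  classes aggregating several surveyed landscape subtypes use the
  area-weighted mean of subtype scores (`av_class_score()`).

The default per-class parameter table (`es_params_default()`) holds plausible
arid-region magnitudes chosen once for the synthetic setting — e.g. bare land
has vegetation factor 1 (no protection) and near-zero carbon; forest carries
the largest carbon pools and the highest aesthetic score; grassland's
moderate 2.5 score reflects an area-weighted mix of high-scoring alpine
meadow and low-scoring desert grassland. Every model takes the table as an
argument; none of the defaults is calibrated to data.

## Interactions

Regional series are min-max normalized per service (constant series map to
all zeros — the convention that keeps a flat flower petal at the origin
rather than undefined). `classify_regional_trends()` labels a service
unchanged when its net relative change is within 1% (configurable), mixed
when the movement against the net direction exceeds the net change itself
(such series are excluded from pairing with a warning), and otherwise
increase/decrease; pair labels follow the standard definitions (two like
signs = synergy, opposite signs = trade-off, unchanged = neutral).

Grid-scale coding assigns digit 1/2/3 (increase/decrease/unchanged) per
service with a per-pixel tolerance ε, default 0 — raw sign of the change —
since the regional threshold already absorbs noise at the aggregate level;
both tolerances are configurable because the choice is genuinely open. The
six digits concatenate in the fixed order WY, CP, SC, SF, CS, AV into one of
3⁶ = 729 codes (a recorded package convention; the overlay itself is
order-agnostic). Human-readable labels list increased services with `+`, then
decreased with `-` (display order SC, CP, CS, AV, WY, SF, following the
figure-legend convention of such studies). The area filter drops legend
classes whose summed area is not **strictly** greater than the threshold
(default 40 km²; "over" is read as `>`, so 4000 pixels of 100 m at exactly
40 km² are dropped and 4001 retained). `attribute_causes()` cross-tabulates
interaction classes against land-use transitions and reports the dominant
transition per class.

## Numerical choices and degenerate inputs

* Row-stochasticity is validated to 1e-9 everywhere; proportions must sum to
  1 within 1e-9.
* Matrix roots: complex parts below 1e-8 are discarded silently; anything
  larger, or negative entries, marks the result as regularized in metadata.
* `ca_allocate()` convergence: every class within `demand_tolerance`
  (default 0.5%) of demand; infeasible demand (e.g. a demanded class whose
  every conversion is cost-forbidden) terminates at the iteration cap and is
  reported through `converged = FALSE` plus the residual deficit — never by
  silently relaxing the constraint.
* Rasters are plain matrices with grid metadata; any cross-layer operation
  on mismatched dimensions or pixel sizes fails with an error naming both
  grids. Serialization uses the ESRI ASCII grid text format with full double
  precision plus a JSON sidecar (class legend, units, year), making
  write/read roundtrips value-exact.
* Areas are planar: `pixel_count × pixel_size²` (a projected planar
  coordinate system is assumed throughout).

## Problem sizes

The test suite and the bundled analysis scripts run the generator at 60×60
to 100×100 pixels (0.36-1 km² per 100 m pixel grid cell, 36-100 km²
extents), Markov parameter-recovery checks at 10⁵ pixels, and the end-to-end
pipeline at 30×30 to 50×50. These sizes were chosen so that every stage's
statistical checks (law-of-large-numbers recovery, demand satisfaction,
AUC/kappa fixtures) are comfortably resolved while a full run stays in the
seconds range.

## Known limitations

* The calibration-period dynamic used to exercise the pipeline is spatially
  independent per pixel, so CA validation kappa mostly reflects persistence
  plus class totals; on real data the CA's spatial skill would be the
  interesting quantity.
* The USLE/RWEQ/Budyko/Miami sub-factor formulations are standard published
  stand-ins, configurable and bypassable; absolute service magnitudes on the
  synthetic landscape are not comparable to any real region's.
* The per-pixel six-digit coding treats services symmetrically; it does not
  weight them by importance or value.
* No hydrological routing, sediment delivery, seasonal stepping, or economic
  valuation — the analysis is annual and biophysical.
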