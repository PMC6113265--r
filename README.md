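# modses

Scenario analysis of land-use change and ecosystem-service (ES) interactions
in mountain-oasis-desert landscapes, as a tested, reusable R pipeline.

## What this is for

Arid-region land policy moves land between six cover classes — cropland,
forest, grassland, water, built-up, bare — and every move shifts a bundle of
services at once: water yield (WY), crop production (CP), soil conservation
(SC), sand fixation (SF), carbon sequestration (CS), aesthetic value (AV).
`modses` implements the full chain of a multi-service scenario analysis for
landscape ecologists who want the method itself reproducible and testable
without any geodata download:

1. **Land demand** — Markov chain on the land-use transition matrix
   `a_{t+1} = a_t P`, with policy scenarios (business-as-usual BAU, economic
   development ED, ecological conservation EC) expressed as multiplicative
   modifiers on specific conversion probabilities (e.g. ED: bare→cropland
   +50%, cropland→built-up +200%), renormalized through the diagonal so the
   stated relative changes are preserved exactly; multi-year matrices are
   split into projection steps through the principal matrix root.
2. **Spatial allocation** — FLUS-style cellular automaton: per-pixel
   combined probability = ANN suitability × neighborhood enrichment ×
   self-adaptive inertia × conversion-cost gate, seeded roulette-wheel
   selection, hard demand gating; validated with rank-based ROC AUC and
   Cohen's kappa.
3. **Service quantification** — per-pixel models:
   `WY = (1 − AET/P)·P` with a Budyko-Zhang AET curve;
   `CP = P_v · I_zrd` with Miami-type climatic productivity;
   USLE `A_c = R·K·L·S·(1 − C·P_s)`;
   RWEQ `ΔQ = Q_0 − Q_v` with `Q_max = 109.8·Π`, `S = 105.71·Π^{−0.3711}`,
   `Q(x) = (2x/S²)·Q_max·e^{−(x/S)²}`;
   carbon `CT = Σ_j (C_above + C_below + C_soil + C_dead)_j · S_j`;
   survey-score aesthetic value with area-weighted subtype aggregation.
4. **Interactions** — regional min-max-normalized trend series
   (flower-diagram data) with synergy/trade-off/neutral pair labels, and a
   per-pixel six-digit overlay code (digit 1/2/3 = increase/decrease/
   unchanged per service, fixed order WY CP SC SF CS AV), filtered by summed
   area and attributed to the land-use transitions beneath each interaction
   class.

A seed-reproducible synthetic landscape generator (elevation gradient,
orographic precipitation, riverine oasis corridor, zone-conditional land
cover at a configurable composition) makes every stage testable end-to-end.

## Worked example

```r
library(modses)
cfg <- pipeline_config(nrow = 50, ncol = 50, seed = 1, min_area_km2 = 0.25)
res <- run_pipeline(cfg)

round(res$validation$roc_auc, 3)
#>  cropland    forest grassland     water     built      bare
#>     0.790     0.828     0.717     0.999     0.962     0.810
round(res$validation$kappa, 3)
#> [1] 0.876

round(res$scenarios$ED$series, 1)      # whole-area totals per year
#>            WY      CP      SC     SF      CS     AV
#> 2015 118792.8 25924.7 3587191 3358.2 16512.5 4925.5
#> 2025 116388.5 31732.3 3620204 3554.9 16730.9 5048.1
#> 2035 114321.3 36642.5 3653234 3691.9 16894.2 5152.9

res$scenarios$ED$trends$trend
#>         WY         CP         SC         SF         CS         AV
#> "decrease" "increase" "increase" "increase" "increase" "increase"

head(res$scenarios$ED$codes$legend[, c("label", "n", "area_km2")], 3)
#>                      label    n area_km2
#> 1                no change 2350    23.50
#> 2     SC+ CS+ AV+ SF+, WY-   60     0.60
#> 3 SC+ CP+ CS+ AV+ SF+, WY-   39     0.39

res$scenarios$ED$causes$dominant
#>          interaction            transition       pct
#> 1             211111      bare -> cropland 100.00000
#> 2             231111         bare -> built  95.00000
#> ...
```

Reading: under the economic-development scenario water yield falls while the
other services rise (reclaimed bare land evapotranspires more), so WY trades
off against a four-to-five-service synergy; the dominant interaction classes
sit on bare→cropland and bare→built-up conversions in the oasis corridor.
The suitability AUCs and the back-allocation kappa certify the ANN-CA stage
on this landscape; the interaction legend is the flower-diagram/overlay
output at grid scale.

The `analysis/` directory holds the same workflow as six numbered scripts
(landscape → demand → suitability → allocation → quantification →
interactions) on a 100×100 landscape, each writing its tables and rasters
under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

## Layout

- `R/` — synthetic landscapes, Markov/scenario demand, ANN-CA allocation,
  the six service models, interaction coding, pipeline driver and ASCII-grid
  raster I/O.
- `analysis/` — the numbered workflow scripts.
- `tests/testthat/` — unit, property and acceptance tests (closed-form
  fixtures, law-of-large-numbers recovery, demand-satisfaction, bijection
  and null end-to-end checks).
- `vignettes/mods-scenario-pipeline.Rmd` — the methods vignette: model
  assumptions, parameter defaults and units, numerical choices, what the
  synthetic generator does and does not emulate, limitations.
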