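#' Default per-class ecosystem-service parameter table
#'
#' One row per land-use class with the parameters the six service models
#' consume: `kc` (evapotranspiration coefficient scaling reference ET in the
#' Budyko curve), `w` (plant-available-water coefficient), `c_cover` /
#' `p_support` (USLE cover and support-practice factors, `[0, 1]`), `c_veg`
#' (RWEQ vegetation factor, `(0, 1]`; 1 = bare), four carbon-pool densities
#' in kg C m-2 (`c_above`, `c_below`, `c_soil`, `c_dead`), and the mean
#' aesthetic survey score `av_score` in `[0, 5]`. Values are plausible
#' arid-region defaults; every model accepts a caller-supplied table.
#'
#' @return Data frame keyed by `class`.
#' @export
es_params_default <- function() {
  data.frame(
    class     = mods_classes(),
    kc        = c(0.95, 1.00, 0.75, 1.05, 0.30, 0.20),
    w         = c(2.0, 3.0, 1.5, 0.5, 0.2, 0.3),
    c_cover   = c(0.22, 0.003, 0.05, 0.0, 0.01, 0.45),
    p_support = c(0.35, 1.0, 1.0, 0.0, 1.0, 1.0),
    c_veg     = c(0.25, 0.10, 0.30, 0.20, 0.80, 1.00),
    c_above   = c(0.90, 6.00, 0.35, 0.00, 0.10, 0.02),
    c_below   = c(0.20, 1.50, 1.60, 0.00, 0.00, 0.02),
    c_soil    = c(8.00, 12.00, 9.00, 0.00, 3.00, 1.50),
    c_dead    = c(0.30, 1.00, 0.10, 0.00, 0.00, 0.00),
    av_score  = c(3.8, 4.5, 2.5, 4.2, 2.0, 1.0))
}

lookup_param <- function(params, classes, col) {
  i <- match(classes, params$class)
  if (anyNA(i)) {
    stop("class missing from parameter table: ",
         paste(classes[is.na(i)], collapse = ", "))
  }
  params[[col]][i]
}

per_pixel_class_value <- function(landuse, values) {
  matrix(values[as.vector(landuse$codes)], nrow(landuse$codes),
         ncol(landuse$codes))
}

#' Budyko-type actual evapotranspiration
#'
#' The Zhang formulation of the Budyko curve:
#' `AET/P = (1 + w phi) / (1 + w phi + 1/phi)` with aridity
#' `phi = kc * ET0 / P`, which keeps the evaporative fraction in `[0, 1)`
#' for all inputs (`AET -> 0` as `ET0 -> 0`; `AET -> P` as aridity grows).
#'
#' @param precip Precipitation (mm/a), matrix or scalar (> 0 where used).
#' @param et0 Reference ET (mm/a).
#' @param kc Per-pixel (or scalar) evapotranspiration coefficient.
#' @param w Per-pixel (or scalar) plant-available-water coefficient.
#' @return AET (mm/a), same shape as the inputs.
#' @export
budyko_zhang_aet <- function(precip, et0, kc = 1, w = 1) {
  phi <- kc * et0 / precip
  frac <- ifelse(phi <= 0, 0, (1 + w * phi) / (1 + w * phi + 1 / phi))
  frac * precip
}

#' Water yield by annual water balance
#'
#' `Y = (1 - AET/P) * P` per pixel. AET comes either from a caller-supplied
#' raster or from the Budyko-Zhang curve of `ET0/P` with the per-class `kc`
#' and `w` parameters. Pixels with `P = 0` yield 0 and are counted in the
#' `"flagged_pixels"` attribute.
#'
#' @param precip Precipitation raster (mm/a, matrix).
#' @param landuse Aligned [lu_map()].
#' @param et0 Reference-ET raster (mm/a); required unless `aet` is given.
#' @param aet Optional precomputed AET raster (mm/a), bypassing the Budyko
#'   sub-model; values are clamped into `[0, P]`.
#' @param params Per-class parameter table (see [es_params_default()]).
#' @param year Year tag for the output layer.
#' @return [es_layer()] `"WY"` in mm/a, `0 <= Y <= P` everywhere.
#' @export
water_yield <- function(precip, landuse, et0 = NULL, aet = NULL,
                        params = es_params_default(), year = NA_integer_) {
  check_aligned(landuse, precip)
  if (is.null(aet)) {
    if (is.null(et0)) stop("either et0 or aet must be supplied")
    kc <- per_pixel_class_value(landuse, lookup_param(params, landuse$classes, "kc"))
    w <- per_pixel_class_value(landuse, lookup_param(params, landuse$classes, "w"))
    aet <- budyko_zhang_aet(precip, et0, kc, w)
  }
  aet <- pmin(pmax(aet, 0), pmax(precip, 0))
  y <- ifelse(precip <= 0, 0, (1 - aet / precip) * precip)
  flagged <- sum(precip <= 0)
  out <- es_layer(y, "WY", units = "mm a-1", year = year,
                  pixel_size = landuse$pixel_size)
  attr(out, "flagged_pixels") <- flagged
  out
}

#' Miami-type climatic productivity
#'
#' Potential net primary productivity as the minimum of a
#' temperature-limited and a precipitation-limited term:
#' `P_T = 3000 / (1 + exp(1.315 - 0.119 T))`,
#' `P_P = 3000 (1 - exp(-0.000664 P))` (g m-2 a-1 dry matter).
#'
#' @param temperature Mean annual temperature (deg C), matrix or scalar.
#' @param precip Annual precipitation (mm), matrix or scalar.
#' @return Climatic productivity, elementwise `min(P_T, P_P)`.
#' @export
miami_productivity <- function(temperature, precip) {
  pt <- 3000 / (1 + exp(1.315 - 0.119 * temperature))
  pp <- 3000 * (1 - exp(-0.000664 * precip))
  pmin(pt, pp)
}

#' Crop production index
#'
#' `CP = P_v * I_zrd` on cropland pixels and 0 elsewhere, where `P_v` is the
#' Miami-type climatic productivity and `I_zrd` the farmland-grading land-use
#' level index in `[0, 1]`.
#'
#' @param landuse [lu_map()] providing the cropland mask.
#' @param temperature,precip Climate rasters (deg C, mm/a).
#' @param izrd Land-use level index raster in `[0, 1]`; must be non-missing
#'   on every cropland pixel.
#' @param year Year tag.
#' @return [es_layer()] `"CP"` (mass index, g m-2 a-1 x index).
#' @export
crop_production <- function(landuse, temperature, precip, izrd,
                            year = NA_integer_) {
  check_aligned(landuse, temperature, precip, izrd)
  if (any(izrd < 0 | izrd > 1, na.rm = TRUE)) {
    stop("I_zrd must lie in [0, 1]")
  }
  crop <- landuse$codes == match("cropland", landuse$classes)
  if (any(crop & is.na(izrd))) stop("I_zrd missing on cropland pixels")
  pv <- miami_productivity(temperature, precip)
  cp <- ifelse(crop, pv * izrd, 0)
  es_layer(cp, "CP", units = "g m-2 a-1 (index)", year = year,
           pixel_size = landuse$pixel_size)
}

#' USLE soil conservation
#'
#' Actual erosion `A = R K L S C P_support`, potential erosion (bare, no
#' support practice) `A_r = R K L S`, and soil conservation
#' `A_c = A_r - A >= 0` (guaranteed since `C * P_support <= 1`).
#'
#' @param r,k,l,s Rainfall-erosivity, soil-erodibility, slope-length and
#'   slope-steepness factor rasters (all non-negative).
#' @param landuse Aligned [lu_map()] supplying per-class `c_cover` and
#'   `p_support`.
#' @param params Per-class parameter table.
#' @param year Year tag.
#' @return [es_layer()] `"SC"` in t km-2 a-1 units of the supplied factors,
#'   with matrices `erosion_actual` and `erosion_potential` attached as
#'   attributes.
#' @export
usle_soil_conservation <- function(r, k, l, s, landuse,
                                   params = es_params_default(),
                                   year = NA_integer_) {
  check_aligned(landuse, r, k, l, s)
  if (any(r < 0) || any(k < 0) || any(l < 0) || any(s < 0)) {
    stop("USLE factors must be non-negative")
  }
  cc <- per_pixel_class_value(landuse,
                              lookup_param(params, landuse$classes, "c_cover"))
  ps <- per_pixel_class_value(landuse,
                              lookup_param(params, landuse$classes, "p_support"))
  if (any(cc < 0 | cc > 1) || any(ps < 0 | ps > 1)) {
    stop("c_cover and p_support must lie in [0, 1]")
  }
  ar <- r * k * l * s
  a <- ar * cc * ps
  ac <- ar - a
  out <- es_layer(ac, "SC", units = "t km-2 a-1", year = year,
                  pixel_size = landuse$pixel_size)
  attr(out, "erosion_actual") <- a
  attr(out, "erosion_potential") <- ar
  out
}

#' RWEQ wind-driven sand transport
#'
#' Closed forms of the revised wind-erosion equation: maximum transport
#' capacity `Qmax = 109.8 (WF EF SCF Ka C)`, critical field length
#' `S = 105.71 (WF EF SCF Ka C)^-0.3711`, and transported mass at downwind
#' distance x, `Q(x) = (2 x / S^2) Qmax exp(-(x/S)^2)`. Where the combined
#' factor product is 0, `Qmax = 0`, `S` is undefined and `Q(x)` is returned
#' as 0 with the pixel counted in `flagged`.
#'
#' @param wf,ef,scf,ka Weather, soil-erodibility, soil-crust and roughness
#'   factor rasters or scalars (non-negative).
#' @param cveg Vegetation cover factor in `(0, 1]` (scalar or raster).
#' @param x Downwind distance (m), the field length.
#' @return List with `qmax`, `s`, `q` (same shape as inputs) and `flagged`
#'   (count of zero-product pixels).
#' @export
rweq_transport <- function(wf, ef, scf, ka, cveg = 1, x = 50) {
  if (any(wf < 0) || any(ef < 0) || any(scf < 0) || any(ka < 0) ||
      any(cveg < 0)) {
    stop("RWEQ factors must be non-negative")
  }
  prod <- wf * ef * scf * ka * cveg
  qmax <- 109.8 * prod
  s <- ifelse(prod > 0, 105.71 * prod^(-0.3711), NA_real_)
  q <- ifelse(prod > 0, (2 * x / s^2) * qmax * exp(-(x / s)^2), 0)
  list(qmax = qmax, s = s, q = q, flagged = sum(prod == 0))
}

#' RWEQ sand fixation
#'
#' `SF = Q0 - Qv`: potential transport with the vegetation factor forced to
#' 1 (bare ground; the crust and roughness factors keep their mapped values)
#' minus actual transport with each class's `c_veg`. Non-negative whenever
#' `c_veg <= 1`.
#'
#' @param wf,ef,scf,ka Wind-factor rasters aligned with `landuse`.
#' @param landuse [lu_map()] supplying per-class `c_veg`.
#' @param params Per-class parameter table; `c_veg` must lie in `(0, 1]`.
#' @param field_length Downwind distance x (m) at which transport is
#'   evaluated.
#' @param year Year tag.
#' @return [es_layer()] `"SF"` in t km-2 a-1.
#' @export
rweq_sand_fixation <- function(wf, ef, scf, ka, landuse,
                               params = es_params_default(),
                               field_length = 50, year = NA_integer_) {
  check_aligned(landuse, wf, ef, scf, ka)
  cveg <- lookup_param(params, landuse$classes, "c_veg")
  if (any(cveg <= 0 | cveg > 1)) stop("c_veg must lie in (0, 1]")
  cv <- per_pixel_class_value(landuse, cveg)
  q0 <- rweq_transport(wf, ef, scf, ka, cveg = 1, x = field_length)$q
  qv <- rweq_transport(wf, ef, scf, ka, cveg = cv, x = field_length)$q
  es_layer(q0 - qv, "SF", units = "t km-2 a-1", year = year,
           pixel_size = landuse$pixel_size)
}

#' Carbon sequestration from per-class pool densities
#'
#' Per-pixel carbon density is the sum of the four pools (aboveground,
#' belowground, soil, dead organic) of the pixel's class; the regional total
#' is `CT = sum_j density_j * area_j`.
#'
#' @param landuse [lu_map()].
#' @param params Per-class table with columns `c_above`, `c_below`, `c_soil`,
#'   `c_dead` (kg C m-2); an error names any map class missing from it.
#' @param year Year tag.
#' @return List: `layer` ([es_layer()] `"CS"`, kg C m-2) and `total` (kg C,
#'   density times pixel area summed over the map).
#' @export
carbon_sequestration <- function(landuse, params = es_params_default(),
                                 year = NA_integer_) {
  pools <- c("c_above", "c_below", "c_soil", "c_dead")
  dens <- rowSums(sapply(pools, function(p)
    lookup_param(params, landuse$classes, p)))
  if (any(dens < 0)) stop("carbon densities must be non-negative")
  layer <- es_layer(per_pixel_class_value(landuse, dens), "CS",
                    units = "kg C m-2", year = year,
                    pixel_size = landuse$pixel_size)
  total <- sum(layer$values) * landuse$pixel_size^2
  list(layer = layer, total = total)
}

#' Area-weighted aesthetic score of a class with subtypes
#'
#' When a legend class aggregates several surveyed landscape subtypes, its
#' score is the area-weighted mean of the subtype scores.
#'
#' @param scores Subtype mean survey scores in `[0, 5]`.
#' @param weights Subtype area weights (summing to 1 within 1e-9).
#' @return The aggregated class score.
#' @export
av_class_score <- function(scores, weights) {
  if (any(scores < 0 | scores > 5)) stop("survey scores must lie in [0, 5]")
  if (abs(sum(weights) - 1) > 1e-9) stop("subtype weights must sum to 1")
  sum(scores * weights)
}

#' Aesthetic-value layer from survey scores
#'
#' Assigns each pixel the mean survey score of its land-use class.
#'
#' @param landuse [lu_map()].
#' @param params Per-class table with `av_score` in `[0, 5]`; an error names
#'   any unscored map class.
#' @param year Year tag.
#' @return [es_layer()] `"AV"` (score, 0-5).
#' @export
aesthetic_value <- function(landuse, params = es_params_default(),
                            year = NA_integer_) {
  scores <- lookup_param(params, landuse$classes, "av_score")
  if (any(scores < 0 | scores > 5)) stop("survey scores must lie in [0, 5]")
  es_layer(per_pixel_class_value(landuse, scores), "AV", units = "score 0-5",
           year = year, pixel_size = landuse$pixel_size)
}

#' Zonal statistics of a service layer
#'
#' Per-zone sum, mean, pixel count and area, plus a whole-area row (`"all"`)
#' equal to the sum over zones.
#'
#' @param layer [es_layer()] (or matrix).
#' @param zones Aligned integer matrix of zone codes.
#' @param zone_names Optional names for the zone codes.
#' @return Data frame with columns `zone`, `n`, `area_km2`, `sum`, `mean`.
#' @export
zonal_totals <- function(layer, zones, zone_names = NULL) {
  vals <- if (inherits(layer, "es_layer")) layer$values else layer
  px <- if (inherits(layer, "es_layer")) layer$pixel_size else NA_real_
  if (!all(dim(vals) == dim(zones))) stop("layer and zones are not aligned")
  zs <- sort(unique(as.vector(zones)))
  rows <- lapply(zs, function(z) {
    sel <- zones == z
    data.frame(zone = if (!is.null(zone_names)) zone_names[z] else
      as.character(z),
      n = sum(sel),
      area_km2 = if (!is.na(px)) sum(sel) * px^2 / 1e6 else NA_real_,
      sum = sum(vals[sel]), mean = mean(vals[sel]))
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(zone = "all", n = sum(out$n),
                        area_km2 = sum(out$area_km2),
                        sum = sum(out$sum), mean = mean(vals)))
}

#' Standard USLE factor rasters from a synthetic landscape
#'
#' Shipped default sub-models for the USLE factors: a Wischmeier-type annual
#' rainfall erosivity `R = 0.0483 P^1.61` (MJ mm ha-1 h-1 a-1 from annual
#' precipitation in mm), an EPIC-style erodibility K from texture fractions
#' and organic matter, and slope-length/steepness factors from the DEM
#' (`L = (lambda / 22.13)^0.5` with the pixel as slope length,
#' `S = (sin(theta) / 0.0896)^1.3`). All models accept precomputed rasters
#' instead; these defaults exist so the pipeline runs end-to-end on synthetic
#' landscapes.
#'
#' @param bundle `landscape_bundle`.
#' @return List of matrices `r`, `k`, `l`, `s`.
#' @export
usle_factors_from_landscape <- function(bundle) {
  p <- bundle$precipitation
  r <- 0.0483 * p^1.61
  sa <- bundle$soil$sand * 100; si <- bundle$soil$silt * 100
  cl <- bundle$soil$clay * 100; om <- bundle$soil$om
  sn <- 1 - sa / 100
  k_epic <- (0.2 + 0.3 * exp(-0.0256 * sa * (1 - si / 100))) *
    (si / (cl + si))^0.3 *
    (1 - 0.25 * om / (om + exp(3.72 - 2.95 * om))) *
    (1 - 0.7 * sn / (sn + exp(-5.51 + 22.9 * sn)))
  slope_deg <- slope_from_dem(bundle$dem, bundle$pixel_size)
  theta <- slope_deg * pi / 180
  l <- (bundle$pixel_size / 22.13)^0.5
  s <- (sin(theta) / 0.0896)^1.3
  list(r = r, k = k_epic, l = matrix(l, nrow(p), ncol(p)), s = s)
}
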