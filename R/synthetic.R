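#' Configuration for the synthetic mountain-oasis-desert landscape
#'
#' Defines the study conditions the generator reproduces: a north-to-south
#' descending elevation gradient, precipitation increasing with altitude, a
#' riverine oasis corridor, and a land-cover composition matching the 2015
#' Altay-like mix (34.9% grassland, 7.3% forest, 3.6% cropland, 52.3% bare
#' land, 1.9% water + built-up).
#'
#' @param nrow,ncol Grid dimensions (>= 20 each).
#' @param pixel_size Pixel edge length in metres (nominal 100 m).
#' @param proportions Named target class proportions over [mods_classes()];
#'   must sum to 1 within 1e-9.
#' @param elev_range Elevation range in metres, `c(min, max)`.
#' @param precip_base Precipitation (mm/a) at the lowest elevation.
#' @param precip_lapse Precipitation increase per metre of elevation (mm/m).
#' @param seed Integer seed; mandatory.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(nrow = 100, ncol = 100, pixel_size = 100,
                             proportions = c(cropland = 0.036, forest = 0.073,
                                             grassland = 0.349, water = 0.012,
                                             built = 0.007, bare = 0.523),
                             elev_range = c(400, 3500),
                             precip_base = 120, precip_lapse = 0.05,
                             seed = NULL) {
  if (is.null(seed)) stop("seed is mandatory in synthetic_config()")
  if (nrow < 20 || ncol < 20) stop("grid too small: need at least 20x20")
  cls <- mods_classes()
  if (!setequal(names(proportions), cls)) {
    stop("proportions must be named over all classes: ",
         paste(cls, collapse = ", "))
  }
  proportions <- proportions[cls]
  if (any(proportions < 0)) stop("invalid proportions: negative entry")
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("invalid proportions: sum is ", format(sum(proportions)),
         ", must be 1 within 1e-9")
  }
  structure(list(nrow = nrow, ncol = ncol, pixel_size = pixel_size,
                 proportions = proportions, elev_range = elev_range,
                 precip_base = precip_base, precip_lapse = precip_lapse,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Spatially correlated Gaussian field: white noise smoothed with a Gaussian
# kernel (EBImage::gblur), rescaled to unit sd. The noise is generated on a
# padded grid so the blur kernel fits whatever grid size is requested, then
# cropped back.
gaussian_field <- function(nrow, ncol, sigma = 4) {
  pad <- 2 * ceiling(3 * sigma) + 2
  z <- matrix(stats::rnorm((nrow + 2 * pad) * (ncol + 2 * pad)),
              nrow + 2 * pad, ncol + 2 * pad)
  s <- EBImage::gblur(z, sigma = sigma)
  s <- s[pad + seq_len(nrow), pad + seq_len(ncol), drop = FALSE]
  s / stats::sd(s)
}

# Euclidean distance (in metres) from every pixel to the nearest TRUE pixel.
# EBImage::distmap measures to the nearest zero pixel, so invert the mask.
distance_to <- function(mask, pixel_size) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(matrix(as.numeric(!mask), nrow(mask), ncol(mask)))
  as.matrix(d) * pixel_size
}

# Slope (degrees) from a DEM by central differences.
slope_from_dem <- function(dem, pixel_size) {
  nr <- nrow(dem); nc <- ncol(dem)
  pad <- function(m, dr, dc) {
    r <- pmin(pmax(seq_len(nr) + dr, 1), nr)
    c <- pmin(pmax(seq_len(nc) + dc, 1), nc)
    m[r, c, drop = FALSE]
  }
  dzdy <- (pad(dem, 1, 0) - pad(dem, -1, 0)) / (2 * pixel_size)
  dzdx <- (pad(dem, 0, 1) - pad(dem, 0, -1)) / (2 * pixel_size)
  atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
}

#' Generate a synthetic mountain-oasis-desert landscape
#'
#' Builds a seed-reproducible [LandscapeBundle]-style list: a DEM descending
#' from north (top rows) to south, a meandering river running south from the
#' mountain front, elevation-tercile zonation with a river-buffer oasis
#' corridor, precipitation increasing with altitude plus correlated noise,
#' temperature/reference-ET decreasing/increasing with descent, soil and
#' wind-factor stacks, and a categorical land-use map placed by
#' zone-conditional priors then filled to hit the target composition exactly
#' (realized proportions differ from targets only by integer rounding).
#'
#' @param config A [synthetic_config()].
#' @return A list of class `landscape_bundle` with elements `landuse_t0`
#'   ([lu_map()]), `dem`, `precipitation`, `temperature`, `et0` (matrices),
#'   `soil` (list: sand, silt, clay, om), `wind` (list: wf, ef, scf, ka),
#'   `zones` (integer matrix, 1 mountain / 2 oasis / 3 desert), `river`
#'   (logical matrix), `pixel_size`, and `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed, {
    nr <- config$nrow; nc <- config$ncol; px <- config$pixel_size
    cls <- mods_classes()
    elo <- config$elev_range[1]; ehi <- config$elev_range[2]

    # DEM: linear north->south descent plus correlated relief
    base <- matrix(rep(seq(1, 0, length.out = nr), nc), nr, nc)
    relief <- gaussian_field(nr, nc, sigma = max(3, round(min(nr, nc) / 20)))
    dem <- elo + (ehi - elo) * pmin(pmax(base + 0.12 * relief, 0), 1)

    # River: random-walk column path from the mountain front to the south edge
    river <- matrix(FALSE, nr, nc)
    steps <- sample(c(-1L, 0L, 0L, 1L), nr, replace = TRUE)
    col_pos <- pmin(pmax(round(nc / 2) + cumsum(steps), 2L), nc - 1L)
    for (r in seq_len(nr)) river[r, col_pos[r]] <- TRUE
    dist_river <- distance_to(river, px)

    # Zones by elevation terciles; oasis = low band near the river
    q <- stats::quantile(dem, c(1 / 3, 2 / 3))
    zones <- matrix(3L, nr, nc)                      # desert
    zones[dem >= q[2]] <- 1L                         # mountain
    oasis_buffer <- max(5, round(min(nr, nc) / 8)) * px
    zones[dem < q[2] & dist_river <= oasis_buffer] <- 2L  # oasis

    # Climate drivers
    precipitation <- config$precip_base +
      config$precip_lapse * (dem - elo) +
      10 * gaussian_field(nr, nc, sigma = 5)
    precipitation <- pmax(precipitation, 5)
    temperature <- 5 - 6.5 * (dem - elo) / 1000 +
      0.8 * gaussian_field(nr, nc, sigma = 5)
    et0 <- pmax(1050 - 0.16 * (dem - elo) + 40 * gaussian_field(nr, nc, 5), 150)

    # Soils: sandier and poorer in the desert, more organic matter upslope
    zf <- function(mountain, oasis, desert) {
      out <- matrix(desert, nr, nc)
      out[zones == 1L] <- mountain; out[zones == 2L] <- oasis
      out
    }
    clamp01 <- function(m) pmin(pmax(m, 0.01), 0.99)
    sand <- clamp01(zf(0.35, 0.45, 0.70) + 0.05 * gaussian_field(nr, nc, 4))
    clay <- clamp01(zf(0.25, 0.20, 0.10) + 0.03 * gaussian_field(nr, nc, 4))
    silt <- pmax(1 - sand - clay, 0.01)
    om <- pmax(zf(3.0, 1.5, 0.4) + 0.3 * gaussian_field(nr, nc, 4), 0.05)

    # Wind-factor stack: erosive weather in the desert lowlands
    wf <- pmax(zf(8, 25, 60) + 5 * gaussian_field(nr, nc, 5), 0.5)
    ef <- clamp01(zf(0.25, 0.35, 0.55) + 0.05 * gaussian_field(nr, nc, 4))
    scf <- clamp01(zf(0.6, 0.5, 0.8) + 0.05 * gaussian_field(nr, nc, 4))
    ka <- clamp01(zf(0.5, 0.7, 0.9) + 0.05 * gaussian_field(nr, nc, 4))

    # Land use: zone-conditional priors scored per class, then greedy fill to
    # exact target counts (smallest classes placed first).
    n <- nr * nc
    target <- round(config$proportions * n)
    # make counts sum exactly to n by adjusting the largest class
    target[which.max(target)] <- target[which.max(target)] + (n - sum(target))
    score <- matrix(0, n, length(cls), dimnames = list(NULL, cls))
    noise <- function() 0.3 * stats::rnorm(n)
    zv <- as.vector(zones); dr <- as.vector(dist_river); dv <- as.vector(dem)
    rel_elev <- (dv - elo) / (ehi - elo)
    score[, "water"] <- -dr / px + noise()
    score[, "built"] <- ifelse(zv == 2L, 2, -2) - 0.5 * dr / (px * 10) + noise()
    score[, "cropland"] <- ifelse(zv == 2L, 2, ifelse(zv == 3L, -1, -3)) -
      dr / (px * 20) + noise()
    score[, "forest"] <- ifelse(zv == 1L, 2, -2) - 2 * abs(rel_elev - 0.75) +
      noise()
    score[, "grassland"] <- ifelse(zv == 1L, 1.5, ifelse(zv == 3L, 0, 0.5)) -
      2 * abs(rel_elev - 0.45) + noise()
    score[, "bare"] <- ifelse(zv == 3L, 2, -2) - rel_elev + noise()
    codes <- integer(n)
    for (cl in names(sort(target))) {
      k <- target[cl]
      if (k == 0) next
      free <- which(codes == 0L)
      pick <- free[order(score[free, cl], decreasing = TRUE)[seq_len(k)]]
      codes[pick] <- match(cl, cls)
    }
    landuse <- lu_map(matrix(codes, nr, nc), classes = cls, pixel_size = px)

    structure(list(
      landuse_t0 = landuse, dem = dem, precipitation = precipitation,
      temperature = temperature, et0 = et0,
      soil = list(sand = sand, silt = silt, clay = clay, om = om),
      wind = list(wf = wf, ef = ef, scf = scf, ka = ka),
      zones = zones, river = river, pixel_size = px, config = config),
      class = "landscape_bundle")
  })
}

#' Draw a paired land-use map from a Markov transition matrix
#'
#' Fixture generator for transition-matrix estimation: each pixel's initial
#' class is drawn from `init_probs`, and its final class from the initial
#' class's row of the matrix, independently across pixels.
#'
#' @param matrix A [transition_matrix()] (row-stochastic).
#' @param n_pixels Number of pixels (0 allowed: returns empty maps).
#' @param seed Integer seed.
#' @param init_probs Initial class distribution; default uniform.
#' @return List with integer vectors `map_t0`, `map_t1` (class codes, with the
#'   class legend in attribute `"classes"`).
#' @export
generate_markov_pair <- function(matrix, n_pixels, seed,
                                 init_probs = NULL) {
  validate_transition_matrix(matrix)
  k <- length(matrix$classes)
  if (is.null(init_probs)) init_probs <- rep(1 / k, k)
  if (n_pixels == 0) {
    empty <- structure(integer(0), classes = matrix$classes)
    return(list(map_t0 = empty, map_t1 = empty))
  }
  with_local_seed(seed, {
    t0 <- sample.int(k, n_pixels, replace = TRUE, prob = init_probs)
    t1 <- integer(n_pixels)
    for (i in seq_len(k)) {
      idx <- which(t0 == i)
      if (length(idx)) {
        t1[idx] <- sample.int(k, length(idx), replace = TRUE,
                              prob = matrix$probs[i, ])
      }
    }
    list(map_t0 = structure(t0, classes = matrix$classes),
         map_t1 = structure(t1, classes = matrix$classes))
  })
}

#' Evolve a land-use map one Markov step
#'
#' Draws each pixel's next class independently from its current class's row
#' of the transition matrix. Used to synthesize a calibration-period map
#' pair with known dynamics; an identity matrix returns the map unchanged.
#'
#' @param map An [lu_map()] whose classes match the matrix.
#' @param matrix A [transition_matrix()].
#' @param seed Integer seed.
#' @return An [lu_map()] on the same grid.
#' @export
markov_evolve_map <- function(map, matrix, seed) {
  validate_transition_matrix(matrix)
  if (!identical(map$classes, matrix$classes)) {
    stop("map and matrix class sets differ")
  }
  k <- length(map$classes)
  codes <- as.vector(map$codes)
  with_local_seed(seed, {
    out <- codes
    for (i in seq_len(k)) {
      idx <- which(codes == i)
      if (!length(idx)) next
      p <- matrix$probs[i, ]
      if (p[i] == 1) next  # identity row: no draw, bit-stable
      out[idx] <- sample.int(k, length(idx), replace = TRUE, prob = p)
    }
    lu_map(base::matrix(out, nrow(map$codes), ncol(map$codes)),
           classes = map$classes, pixel_size = map$pixel_size)
  })
}

#' Generate a driving-factor stack for suitability training
#'
#' Produces `n_factors` aligned continuous rasters: slope from the DEM,
#' distance to water, distance to built-up, elevation, precipitation,
#' temperature, reference ET, then spatially correlated noise factors up to
#' the requested count (16 by default, the count commonly used to train
#' land-use suitability networks).
#'
#' @param bundle A `landscape_bundle` from [generate_landscape()].
#' @param n_factors Number of factors (>= 3).
#' @param seed Integer seed (for the noise factors).
#' @return 3-D array `[nrow, ncol, n_factors]` with factor names in the third
#'   dimnames; every value finite.
#' @export
generate_driving_factors <- function(bundle, n_factors = 16, seed = 1L) {
  stopifnot(inherits(bundle, "landscape_bundle"))
  if (n_factors < 3) stop("n_factors must be at least 3")
  px <- bundle$pixel_size
  lu <- bundle$landuse_t0$codes
  water_code <- match("water", bundle$landuse_t0$classes)
  built_code <- match("built", bundle$landuse_t0$classes)
  cap <- function(m) {  # distances on maps lacking the class: finite fallback
    m[!is.finite(m)] <- max(dim(lu)) * px
    m
  }
  base <- list(
    slope = slope_from_dem(bundle$dem, px),
    dist_water = cap(distance_to(lu == water_code, px)),
    dist_built = cap(distance_to(lu == built_code, px)),
    elevation = bundle$dem,
    precipitation = bundle$precipitation,
    temperature = bundle$temperature,
    et0 = bundle$et0)
  with_local_seed(seed, {
    out <- base[seq_len(min(n_factors, length(base)))]
    i <- 1
    while (length(out) < n_factors) {
      out[[paste0("noise", i)]] <- gaussian_field(nrow(lu), ncol(lu), sigma = 4)
      i <- i + 1
    }
    arr <- array(unlist(out, use.names = FALSE),
                 dim = c(nrow(lu), ncol(lu), n_factors),
                 dimnames = list(NULL, NULL, names(out)))
    stopifnot(all(is.finite(arr)))
    arr
  })
}
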