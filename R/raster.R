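#' Land-use classes used throughout the package
#'
#' The fixed six-class legend for categorical land-use rasters. Integer codes
#' 1..6 in a land-use map index into this vector.
#'
#' @return Character vector of class names in code order.
#' @export
mods_classes <- function() {
  c("cropland", "forest", "grassland", "water", "built", "bare")
}

#' Canonical ecosystem-service order
#'
#' Fixed digit order used by the six-digit interaction codes: water yield
#' (WY), crop production (CP), soil conservation (SC), sand fixation (SF),
#' carbon sequestration (CS), aesthetic value (AV).
#'
#' @return Character vector of the six service abbreviations.
#' @export
es_order <- function() {
  c("WY", "CP", "SC", "SF", "CS", "AV")
}

#' Categorical land-use map
#'
#' A light container for a categorical raster: an integer matrix of class
#' codes plus the class legend and the pixel size in metres. All layers in a
#' run share one planar grid; areas are `pixel_count * pixel_size^2`.
#'
#' @param codes Integer matrix of class codes (1-based indices into `classes`).
#' @param classes Character vector of class names; defaults to [mods_classes()].
#' @param pixel_size Pixel edge length in metres.
#' @return An object of class `lu_map` with fields `codes`, `classes`,
#'   `pixel_size`.
#' @export
lu_map <- function(codes, classes = mods_classes(), pixel_size = 100) {
  if (!is.matrix(codes)) codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  bad <- codes[!is.na(codes)]
  if (length(bad) && (min(bad) < 1L || max(bad) > length(classes))) {
    stop("land-use codes must lie in 1..", length(classes))
  }
  structure(list(codes = codes, classes = classes, pixel_size = pixel_size),
            class = "lu_map")
}

#' @export
print.lu_map <- function(x, ...) {
  cat("<lu_map> ", nrow(x$codes), "x", ncol(x$codes),
      " @ ", x$pixel_size, " m\n", sep = "")
  tab <- class_proportions(x)
  print(round(tab, 4))
  invisible(x)
}

#' Realized class proportions of a land-use map
#'
#' @param map An [lu_map()].
#' @return Named numeric vector of per-class pixel proportions.
#' @export
class_proportions <- function(map) {
  n <- tabulate(map$codes, nbins = length(map$classes))
  stats::setNames(n / sum(n), map$classes)
}

#' Per-class pixel counts of a land-use map
#' @param map An [lu_map()].
#' @return Named integer vector of pixel counts.
#' @export
class_counts <- function(map) {
  stats::setNames(tabulate(map$codes, nbins = length(map$classes)),
                  map$classes)
}

#' Continuous ecosystem-service layer
#'
#' @param values Numeric matrix of per-pixel service values.
#' @param service Service abbreviation (one of [es_order()], or any label).
#' @param units Unit string, e.g. `"mm a-1"` or `"t km-2 a-1"`.
#' @param year Year tag (integer or NA).
#' @param pixel_size Pixel edge length in metres.
#' @return An object of class `es_layer`.
#' @export
es_layer <- function(values, service, units = "", year = NA_integer_,
                     pixel_size = 100) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  structure(list(values = values, service = service, units = units,
                 year = year, pixel_size = pixel_size),
            class = "es_layer")
}

#' @export
print.es_layer <- function(x, ...) {
  cat("<es_layer ", x$service, "> ", nrow(x$values), "x", ncol(x$values),
      " [", x$units, "] year=", x$year, "\n", sep = "")
  cat("  range: ", paste(signif(range(x$values, na.rm = TRUE), 5),
                         collapse = " .. "), "\n", sep = "")
  invisible(x)
}

grid_of <- function(x) {
  if (inherits(x, "lu_map")) {
    list(dim = dim(x$codes), pixel_size = x$pixel_size)
  } else if (inherits(x, "es_layer")) {
    list(dim = dim(x$values), pixel_size = x$pixel_size)
  } else if (is.matrix(x)) {
    list(dim = dim(x), pixel_size = NA_real_)
  } else {
    stop("not a raster-like object")
  }
}

#' Assert that raster layers share one grid
#'
#' Cross-layer operations refuse to run on mismatched grids: any difference in
#' matrix dimensions or (where known) pixel size raises an error naming both
#' grids.
#'
#' @param ... Two or more raster-like objects (`lu_map`, `es_layer`, matrix).
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
check_aligned <- function(...) {
  layers <- list(...)
  g0 <- grid_of(layers[[1]])
  for (i in seq_along(layers)[-1]) {
    g <- grid_of(layers[[i]])
    if (!identical(g$dim, g0$dim) ||
        (!is.na(g$pixel_size) && !is.na(g0$pixel_size) &&
         g$pixel_size != g0$pixel_size)) {
      stop(sprintf(
        "grid mismatch: layer 1 is %dx%d @ %s m, layer %d is %dx%d @ %s m",
        g0$dim[1], g0$dim[2], format(g0$pixel_size),
        i, g$dim[1], g$dim[2], format(g$pixel_size)))
    }
  }
  invisible(TRUE)
}

#' Write a raster matrix as an ESRI ASCII grid
#'
#' Plain-text single-band raster serialization (`.asc`), with values written
#' at full double precision so that a write/read roundtrip is value-exact.
#' A JSON sidecar (`<path>.json`) records metadata: class legend for
#' categorical maps, units/year for service layers, and any extra fields.
#'
#' @param x Matrix, [lu_map()] or [es_layer()].
#' @param path Output path (conventionally ending in `.asc`).
#' @param pixel_size Pixel size in metres (taken from the object if present).
#' @param nodata Value written for `NA` cells.
#' @param sidecar Named list of extra metadata for the JSON sidecar.
#' @return Invisibly, the path.
#' @export
write_ascii_grid <- function(x, path, pixel_size = NULL, nodata = -9999,
                             sidecar = list()) {
  meta <- list()
  if (inherits(x, "lu_map")) {
    meta <- list(type = "categorical", classes = x$classes)
    pixel_size <- x$pixel_size
    m <- x$codes
  } else if (inherits(x, "es_layer")) {
    meta <- list(type = "continuous", service = x$service, units = x$units,
                 year = x$year)
    pixel_size <- x$pixel_size
    m <- x$values
  } else {
    m <- as.matrix(x)
    if (is.null(pixel_size)) stop("pixel_size required for a bare matrix")
    meta <- list(type = "continuous")
  }
  header <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %s", format(pixel_size, digits = 17)),
    sprintf("NODATA_value %s", format(nodata, digits = 17)))
  vals <- m
  vals[is.na(vals)] <- nodata
  body <- apply(vals, 1, function(r) paste(formatC(r, format = "g", digits = 17),
                                           collapse = " "))
  writeLines(c(header, body), path)
  meta <- c(meta, list(pixel_size = pixel_size, nodata = nodata), sidecar)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ascii_grid()]
#'
#' Reconstructs an [lu_map()] or [es_layer()] from the `.asc` file and its
#' JSON sidecar; without a sidecar, returns a plain matrix with a
#' `pixel_size` attribute.
#'
#' @param path Path to the `.asc` file.
#' @param expect_grid Optional grid (list with `dim`, `pixel_size`) the layer
#'   must match; mismatch raises an alignment error naming both grids.
#' @return `lu_map`, `es_layer`, or matrix.
#' @export
read_ascii_grid <- function(path, expect_grid = NULL) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, " "), hdr, ignore.case = TRUE)]
    as.numeric(sub(paste0("^", key, " +"), "", ln, ignore.case = TRUE))
  }
  nc <- val("ncols"); nr <- val("nrows")
  cellsize <- val("cellsize"); nodata <- val("NODATA_value")
  m <- matrix(scan(text = paste(lines[-(1:6)], collapse = "\n"),
                   quiet = TRUE), nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  sidecar_path <- paste0(path, ".json")
  meta <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else list(type = "continuous", pixel_size = cellsize)
  if (!is.null(expect_grid)) {
    if (!identical(as.integer(expect_grid$dim), as.integer(c(nr, nc))) ||
        expect_grid$pixel_size != cellsize) {
      stop(sprintf(
        "grid mismatch: run grid is %dx%d @ %s m, %s is %dx%d @ %s m",
        expect_grid$dim[1], expect_grid$dim[2], format(expect_grid$pixel_size),
        basename(path), nr, nc, format(cellsize)))
    }
  }
  if (identical(meta$type, "categorical")) {
    lu_map(m, classes = meta$classes, pixel_size = meta$pixel_size)
  } else if (!is.null(meta$service)) {
    es_layer(m, service = meta$service, units = meta$units %||% "",
             year = meta$year %||% NA_integer_, pixel_size = meta$pixel_size)
  } else {
    attr(m, "pixel_size") <- meta$pixel_size %||% cellsize
    m
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr with a private RNG stream seeded by `seed`, restoring any
# pre-existing global .Random.seed afterwards.  Every stochastic operation in
# the package routes its randomness through this helper.
with_local_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) stop("a seed is mandatory")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
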