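#' Min-max normalization of a regional series
#'
#' Maps the minimum to 0 and the maximum to 1; a constant series maps to all
#' zeros. Used to put the six services on a common `[0, 1]` scale for the
#' flower-diagram trend series.
#'
#' @param x Numeric vector, length >= 2, finite.
#' @return Normalized vector in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  if (length(x) < 2) stop("series must have length >= 2")
  if (any(!is.finite(x))) stop("series contains non-finite values")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Classify regional ES trends and pairwise interactions
#'
#' Each service's whole-area series is labeled `increase` or `decrease` when
#' its total relative change exceeds `unchanged_threshold` with a consistent
#' sign, `unchanged` when the net change is within the threshold, and
#' `mixed` (excluded from pairing, with a warning) when the movement against
#' the net direction exceeds the net change itself. Pairs of trends map to
#' interactions: two increases or two decreases are a synergy, an increase
#' against a decrease is a trade-off, and any pair involving an unchanged
#' service is neutral.
#'
#' @param series Named list of numeric per-year series (one per service),
#'   all sharing the same years.
#' @param unchanged_threshold Relative net change below which a service is
#'   `unchanged` (default 1%).
#' @return List: `trend` (named character), `pairs` (character matrix of
#'   `synergy` / `trade-off` / `neutral`, `NA` against mixed services).
#' @export
classify_regional_trends <- function(series, unchanged_threshold = 0.01) {
  lens <- lengths(series)
  if (length(unique(lens)) != 1) stop("all series must share the same years")
  trend <- vapply(series, function(v) {
    net <- v[length(v)] - v[1]
    base <- if (abs(v[1]) > 0) abs(v[1]) else max(abs(v), 1e-12)
    if (abs(net) / base <= unchanged_threshold) return("unchanged")
    d <- diff(v)
    against <- sum(pmax(-sign(net) * d, 0))
    if (against > abs(net)) return("mixed")
    if (net > 0) "increase" else "decrease"
  }, character(1))
  if (any(trend == "mixed")) {
    warning("mixed (non-monotone) series excluded from pairing: ",
            paste(names(trend)[trend == "mixed"], collapse = ", "))
  }
  k <- length(series)
  pairs <- matrix(NA_character_, k, k,
                  dimnames = list(names(series), names(series)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      a <- trend[i]; b <- trend[j]
      pairs[i, j] <- if (a == "mixed" || b == "mixed") NA_character_
        else if (a == "unchanged" || b == "unchanged") "neutral"
        else if (a == b) "synergy"
        else "trade-off"
    }
  }
  diag(pairs) <- NA_character_
  list(trend = trend, pairs = pairs)
}

#' Reclassify a service change into increase/decrease/unchanged digits
#'
#' `delta = t1 - t0` per pixel; digit 1 where `delta > epsilon`, 2 where
#' `delta < -epsilon`, 3 otherwise. The default `epsilon = 0` treats any raw
#' increase or decrease as such.
#'
#' @param es_t0,es_t1 Aligned [es_layer()]s of the same service and units.
#' @param epsilon Absolute no-change tolerance (same units as the layers).
#' @return Integer matrix of digits in `{1, 2, 3}`.
#' @export
reclass_change <- function(es_t0, es_t1, epsilon = 0) {
  check_aligned(es_t0, es_t1)
  if (!identical(es_t0$units, es_t1$units)) {
    stop("unit mismatch: ", es_t0$units, " vs ", es_t1$units)
  }
  delta <- es_t1$values - es_t0$values
  digit <- matrix(3L, nrow(delta), ncol(delta))
  digit[delta > epsilon] <- 1L
  digit[delta < -epsilon] <- 2L
  digit
}

#' Overlay six digit rasters into per-pixel interaction codes
#'
#' Concatenates the per-service digits in the fixed order
#' `WY, CP, SC, SF, CS, AV` into a six-character code per pixel; the mapping
#' is bijective with the digit tuple.
#'
#' @param digits Named list of six aligned integer digit matrices (values in
#'   `{1, 2, 3}`), with names covering [es_order()].
#' @param order Service order for the digits; default [es_order()].
#' @param pixel_size Pixel size in metres.
#' @return An `interaction_codes` object: list with `codes` (character
#'   matrix), `es_order`, `pixel_size`, and `legend` (`NULL` until
#'   [filter_codes_by_area()]).
#' @export
encode_overlay <- function(digits, order = es_order(), pixel_size = 100) {
  if (!all(order %in% names(digits))) {
    stop("digit rasters must be named over: ", paste(order, collapse = ", "))
  }
  digits <- digits[order]
  d0 <- digits[[1]]
  for (d in digits) {
    if (!all(dim(d) == dim(d0))) stop("digit rasters are not aligned")
    if (!all(d %in% 1:3)) stop("digits must lie in {1, 2, 3}")
  }
  codes <- matrix(do.call(paste0, lapply(digits, as.vector)),
                  nrow(d0), ncol(d0))
  structure(list(codes = codes, es_order = order, pixel_size = pixel_size,
                 legend = NULL),
            class = "interaction_codes")
}

# Display order of services in the human-readable labels, following the
# figure-legend convention (increases listed before decreases; SC CP CS AV /
# WY SF grouping style).
label_display_order <- function() c("SC", "CP", "CS", "AV", "WY", "SF")

#' Decode a six-digit interaction code into a label
#'
#' Produces a label listing increased services with `+` and decreased
#' services with `-` (unchanged services omitted), e.g. digits
#' `(WY=2, CP=1, SC=1, SF=2, CS=1, AV=1)` give
#' `"SC+ CP+ CS+ AV+, WY- SF-"`. Groups of two or more co-increasing (or
#' co-decreasing) services are synergies; any increase against any decrease
#' is a trade-off.
#'
#' @param code Six-character string of digits in `{1, 2, 3}`.
#' @param order Service order of the digits; default [es_order()].
#' @return List: `label`, `increases`, `decreases`, `synergy_increase`,
#'   `synergy_decrease`, `trade_off`.
#' @export
decode_code <- function(code, order = es_order()) {
  if (!is.character(code) || nchar(code) != length(order) ||
      !grepl(paste0("^[123]{", length(order), "}$"), code)) {
    stop("malformed interaction code: ", code)
  }
  d <- as.integer(strsplit(code, "")[[1]])
  names(d) <- order
  disp <- intersect(label_display_order(), order)
  inc <- disp[d[disp] == 1]
  dec <- disp[d[disp] == 2]
  label <- if (!length(inc) && !length(dec)) "no change" else {
    parts <- c(if (length(inc)) paste(paste0(inc, "+"), collapse = " "),
               if (length(dec)) paste(paste0(dec, "-"), collapse = " "))
    paste(parts, collapse = ", ")
  }
  list(label = label, increases = inc, decreases = dec,
       synergy_increase = length(inc) >= 2,
       synergy_decrease = length(dec) >= 2,
       trade_off = length(inc) >= 1 && length(dec) >= 1)
}

#' Filter interaction codes by summed area
#'
#' Codes whose total pixel area is not strictly greater than `min_area_km2`
#' are collectively relabeled `"other interactions"`; the retained legend is
#' sorted by area descending. Relabeling conserves the total pixel count.
#'
#' @param codes An `interaction_codes` object.
#' @param min_area_km2 Area threshold (strictly "over": `>`, not `>=`).
#' @return The `interaction_codes` object with `legend` (data frame: `code`,
#'   `label`, `n`, `area_km2`, `retained`) and `classes` (character matrix
#'   with dropped codes relabeled `"other interactions"`).
#' @export
filter_codes_by_area <- function(codes, min_area_km2 = 40) {
  stopifnot(inherits(codes, "interaction_codes"))
  if (min_area_km2 <= 0) stop("min_area_km2 must be positive")
  tab <- table(codes$codes)
  px_km2 <- codes$pixel_size^2 / 1e6
  legend <- data.frame(code = names(tab), n = as.integer(tab),
                       area_km2 = as.integer(tab) * px_km2,
                       stringsAsFactors = FALSE)
  legend$retained <- legend$area_km2 > min_area_km2
  legend$label <- vapply(legend$code,
                         function(cd) decode_code(cd, codes$es_order)$label,
                         character(1))
  legend <- legend[order(-legend$area_km2), c("code", "label", "n",
                                              "area_km2", "retained")]
  rownames(legend) <- NULL
  classes <- codes$codes
  drop <- legend$code[!legend$retained]
  classes[classes %in% drop] <- "other interactions"
  codes$legend <- legend
  codes$classes <- classes
  codes
}

#' Attribute interaction classes to land-use transitions
#'
#' Cross-tabulates the (filtered) interaction classes against the land-use
#' transitions `from -> to` between the two dates (`"no transition"` for
#' unchanged pixels), reporting counts, row percentages, and the dominant
#' transition per interaction class.
#'
#' @param codes An `interaction_codes` object (after
#'   [filter_codes_by_area()], so that `classes` exists; otherwise raw codes
#'   are used as classes).
#' @param lu_t0,lu_t1 Aligned [lu_map()]s at the two dates.
#' @return List: `table` (data frame `interaction`, `transition`, `n`,
#'   `pct`), `dominant` (data frame `interaction`, `transition`, `pct`).
#' @export
attribute_causes <- function(codes, lu_t0, lu_t1) {
  stopifnot(inherits(codes, "interaction_codes"))
  check_aligned(lu_t0, lu_t1)
  cls <- codes$classes %||% codes$codes
  if (!all(dim(cls) == dim(lu_t0$codes))) {
    stop("codes and land-use maps are not aligned")
  }
  from <- lu_t0$classes[as.vector(lu_t0$codes)]
  to <- lu_t1$classes[as.vector(lu_t1$codes)]
  trans <- ifelse(from == to, "no transition", paste(from, "->", to))
  tab <- as.data.frame(table(interaction = as.vector(cls),
                             transition = trans),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab <- tab[tab$n > 0, ]
  totals <- tapply(tab$n, tab$interaction, sum)
  tab$pct <- 100 * tab$n / as.numeric(totals[tab$interaction])
  tab <- tab[order(tab$interaction, -tab$n), ]
  rownames(tab) <- NULL
  dominant <- do.call(rbind, lapply(split(tab, tab$interaction), function(g) {
    g[which.max(g$n), c("interaction", "transition", "pct")]
  }))
  rownames(dominant) <- NULL
  list(table = tab, dominant = dominant)
}
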