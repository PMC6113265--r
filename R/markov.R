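#' Land-use transition probability matrix
#'
#' Row-stochastic matrix of per-period probabilities that a pixel of class i
#' becomes class j over `period_years` years.
#'
#' @param probs Square numeric matrix; each row must sum to 1 within 1e-9 and
#'   all entries lie in `[0, 1]`.
#' @param classes Class labels (row/column order).
#' @param period_years Length of the calibration period in years.
#' @return A `transition_matrix` object.
#' @export
transition_matrix <- function(probs, classes = rownames(probs),
                              period_years = 1) {
  probs <- as.matrix(probs)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(probs)))
  dimnames(probs) <- list(classes, classes)
  out <- structure(list(probs = probs, classes = classes,
                        period_years = period_years),
                   class = "transition_matrix")
  validate_transition_matrix(out)
  out
}

validate_transition_matrix <- function(tm) {
  if (!inherits(tm, "transition_matrix")) stop("not a transition_matrix")
  p <- tm$probs
  if (nrow(p) != ncol(p)) stop("transition matrix must be square")
  if (any(p < -1e-12 | p > 1 + 1e-12)) {
    stop("transition probabilities must lie in [0, 1]")
  }
  rs <- rowSums(p)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("transition matrix rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  }
  invisible(tm)
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> ", nrow(x$probs), " classes, period ",
      x$period_years, " years\n", sep = "")
  print(round(x$probs, 4))
  invisible(x)
}

#' Estimate a transition matrix from two dated land-use maps
#'
#' Cross-tabulates aligned maps: `probs[i, j]` is the fraction of pixels of
#' class i at t0 that are class j at t1. Classes absent at t0 receive an
#' identity row (no invented dynamics).
#'
#' @param map_t0,map_t1 Aligned [lu_map()]s (or integer code vectors carrying
#'   a `"classes"` attribute, as returned by [generate_markov_pair()]).
#' @param period_years Years between the two maps.
#' @return A [transition_matrix()].
#' @export
estimate_transition_matrix <- function(map_t0, map_t1, period_years = 1) {
  as_codes <- function(m) {
    if (inherits(m, "lu_map")) list(codes = as.vector(m$codes), cls = m$classes)
    else list(codes = as.integer(m), cls = attr(m, "classes"))
  }
  a <- as_codes(map_t0); b <- as_codes(map_t1)
  cls <- a$cls %||% b$cls %||% as.character(seq_len(max(a$codes, b$codes, 1)))
  if (inherits(map_t0, "lu_map") && inherits(map_t1, "lu_map")) {
    check_aligned(map_t0, map_t1)
    if (!identical(map_t0$classes, map_t1$classes)) {
      stop("maps carry different class sets")
    }
  } else if (length(a$codes) != length(b$codes)) {
    stop("maps have different lengths")
  }
  k <- length(cls)
  counts <- matrix(0, k, k)
  if (length(a$codes)) {
    tab <- table(factor(a$codes, levels = seq_len(k)),
                 factor(b$codes, levels = seq_len(k)))
    counts <- matrix(as.numeric(tab), k, k)
  }
  n0 <- rowSums(counts)
  probs <- counts / ifelse(n0 > 0, n0, 1)
  empty <- n0 == 0
  probs[empty, ] <- 0
  diag(probs)[empty] <- 1
  transition_matrix(probs, classes = cls, period_years = period_years)
}

#' Scenario specification: multiplicative transition-rate modifiers
#'
#' A named set of relative changes applied to specific off-diagonal
#' transition probabilities, e.g. `+0.5` for "increase by 50%", `-1` for
#' "decrease by 100%".
#'
#' @param name Scenario name (conventionally `"BAU"`, `"ED"`, `"EC"`).
#' @param modifiers Data frame with columns `from`, `to`, `change`
#'   (`change >= -1`); BAU uses an empty modifier set.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(name, modifiers = data.frame(
  from = character(), to = character(), change = numeric())) {
  modifiers <- as.data.frame(modifiers)
  stopifnot(all(c("from", "to", "change") %in% names(modifiers)))
  if (any(modifiers$change < -1)) {
    stop("relative_change below -1 would make a probability negative")
  }
  if (any(modifiers$from == modifiers$to)) {
    stop("modifiers must target off-diagonal (from != to) transitions")
  }
  structure(list(name = name, modifiers = modifiers), class = "scenario_spec")
}

#' The three built-in policy scenarios
#'
#' BAU keeps the calibration transition rates. ED (economic development)
#' raises conversion of forest/grassland/water/bare into cropland by 50% and
#' of cropland/forest/grassland/bare into built-up by 200%. EC (ecological
#' conservation) cuts conversion of forest/grassland/water into cropland and
#' built-up by 100%, of bare into cropland and built-up by 50%, and raises
#' conversion of cropland into forest/grassland/water by 80%.
#'
#' @return Named list of three [scenario_spec()]s.
#' @export
default_scenarios <- function() {
  mod <- function(from, to, change) {
    expand.grid(from = from, to = to, change = change,
                stringsAsFactors = FALSE)
  }
  ed <- rbind(
    mod(c("forest", "grassland", "water", "bare"), "cropland", 0.5),
    mod(c("cropland", "forest", "grassland", "bare"), "built", 2.0))
  ec <- rbind(
    mod(c("forest", "grassland", "water"), c("cropland", "built"), -1.0),
    mod("bare", c("cropland", "built"), -0.5),
    mod("cropland", c("forest", "grassland", "water"), 0.8))
  list(BAU = scenario_spec("BAU"),
       ED = scenario_spec("ED", ed),
       EC = scenario_spec("EC", ec))
}

#' Apply scenario modifiers to a transition matrix
#'
#' Each targeted off-diagonal entry p becomes `p * (1 + change)`; the
#' diagonal (stay) entry of the row absorbs the residual so the row still
#' sums to 1, which preserves the stated relative changes on the targeted
#' conversions exactly. If the diagonal would go negative, all off-diagonal
#' entries of that row are rescaled proportionally so the diagonal is
#' exactly 0.
#'
#' @param matrix A [transition_matrix()].
#' @param scenario A [scenario_spec()].
#' @return A modified, row-stochastic [transition_matrix()].
#' @export
apply_scenario_modifiers <- function(matrix, scenario) {
  validate_transition_matrix(matrix)
  stopifnot(inherits(scenario, "scenario_spec"))
  p <- matrix$probs
  for (i in seq_len(nrow(scenario$modifiers))) {
    m <- scenario$modifiers[i, ]
    if (!(m$from %in% matrix$classes) || !(m$to %in% matrix$classes)) {
      stop("modifier names unknown class: ", m$from, " -> ", m$to)
    }
    if (m$change < -1) stop("relative_change below -1 is invalid")
    p[m$from, m$to] <- p[m$from, m$to] * (1 + m$change)
  }
  for (r in seq_len(nrow(p))) {
    off <- sum(p[r, ]) - p[r, r]
    if (off <= 1) {
      p[r, r] <- 1 - off
    } else {
      sel <- setdiff(seq_len(ncol(p)), r)
      p[r, sel] <- p[r, sel] / off
      p[r, r] <- 0
    }
  }
  transition_matrix(p, classes = matrix$classes,
                    period_years = matrix$period_years)
}

#' Split a transition matrix into n equal sub-period steps
#'
#' Returns a matrix Q with `Q^n ~= P`, computed as the principal n-th root
#' through the eigendecomposition. Where the root is not a valid stochastic
#' matrix (complex or negative entries), it is regularized by taking real
#' parts, clipping negatives and renormalizing rows; the achieved Frobenius
#' error `||Q^n - P||_F` and a regularization flag are attached as the
#' `"meta"` attribute.
#'
#' @param matrix A [transition_matrix()].
#' @param n_steps Number of equal steps (`n_steps = 1` returns the input).
#' @return A [transition_matrix()] with `period_years = period / n_steps`.
#' @export
step_split_matrix <- function(matrix, n_steps) {
  validate_transition_matrix(matrix)
  if (n_steps == 1) return(matrix)
  p <- matrix$probs
  e <- eigen(p)
  lambda <- as.complex(e$values)^(1 / n_steps)
  q <- e$vectors %*% diag(lambda, nrow = length(lambda)) %*% solve(e$vectors)
  imag_err <- max(abs(Im(q)))
  q <- Re(q)
  regularized <- imag_err > 1e-8 || any(q < -1e-12)
  q[q < 0] <- 0
  q <- q / rowSums(q)
  qn <- q
  for (i in seq_len(n_steps - 1)) qn <- qn %*% q
  frob <- sqrt(sum((qn - p)^2))
  out <- transition_matrix(q, classes = matrix$classes,
                           period_years = matrix$period_years / n_steps)
  attr(out, "meta") <- list(frobenius_error = frob, regularized = regularized)
  out
}

#' Project per-class land demand through time
#'
#' Markov projection `a_{t+1} = a_t %*% P` applied once per consecutive year
#' pair; the spacing of `years` must equal the matrix's `period_years`.
#' Total area is conserved at every step.
#'
#' @param matrix A [transition_matrix()].
#' @param initial_areas Named non-negative per-class areas (any consistent
#'   unit: km2 or pixel counts).
#' @param years Strictly increasing year vector; `years[1]` is the initial
#'   year.
#' @return A data frame (class `demand_trajectory`) with a `year` column and
#'   one column per class.
#' @export
project_demand <- function(matrix, initial_areas, years) {
  validate_transition_matrix(matrix)
  if (any(initial_areas < 0)) stop("areas must be non-negative")
  if (any(diff(years) <= 0)) stop("years must be strictly increasing")
  gaps <- diff(years)
  if (length(gaps) && any(abs(gaps - matrix$period_years) > 1e-9)) {
    stop("year spacing (", paste(unique(gaps), collapse = ", "),
         ") must equal the matrix period (", matrix$period_years, " years)")
  }
  a <- as.numeric(initial_areas[matrix$classes])
  if (anyNA(a)) stop("initial_areas must be named over all classes")
  out <- matrix(NA_real_, length(years), length(a),
                dimnames = list(NULL, matrix$classes))
  out[1, ] <- a
  for (i in seq_along(years)[-1]) {
    a <- as.numeric(a %*% matrix$probs)
    out[i, ] <- a
  }
  res <- data.frame(year = years, out, check.names = FALSE)
  class(res) <- c("demand_trajectory", "data.frame")
  res
}
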