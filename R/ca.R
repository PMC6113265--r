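#' Cellular-automaton parameters
#'
#' @param neighborhood_weights Per-class weights in `[0, 1]` scaling the
#'   neighborhood-enrichment term; default 0.5 for every class.
#' @param conversion_cost Square 0/1 (or `[0, 1]`) matrix gating transitions:
#'   `conversion_cost[i, j] = 0` forbids converting class i pixels to class j.
#'   The diagonal (staying put) is always treated as allowed. Default: all
#'   transitions allowed.
#' @param window Odd neighborhood window size (>= 3; 3 = Moore neighborhood).
#' @param demand_tolerance Convergence tolerance as a fraction of each
#'   class's demand.
#' @param max_iterations Iteration cap.
#' @param inertia_step Per-iteration multiplicative adjustment of the
#'   self-adaptive inertia coefficient.
#' @param seed Integer seed for the roulette-wheel draws.
#' @return A `ca_params` list.
#' @export
ca_params <- function(neighborhood_weights = NULL, conversion_cost = NULL,
                      window = 3, demand_tolerance = 0.005,
                      max_iterations = 200, inertia_step = 0.1, seed = 1L) {
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  if (demand_tolerance <= 0) stop("demand_tolerance must be positive")
  structure(list(neighborhood_weights = neighborhood_weights,
                 conversion_cost = conversion_cost, window = window,
                 demand_tolerance = demand_tolerance,
                 max_iterations = max_iterations,
                 inertia_step = inertia_step, seed = seed),
            class = "ca_params")
}

# Count of pixels equal to each class inside the w x w window around every
# pixel (centre excluded), by shift-and-sum with zero padding at the edges.
neighborhood_counts <- function(codes, k, window) {
  nr <- nrow(codes); nc <- ncol(codes)
  half <- (window - 1) / 2
  out <- array(0, c(nr, nc, k))
  for (cl in seq_len(k)) {
    ind <- (codes == cl) * 1
    acc <- matrix(0, nr, nc)
    for (dr in -half:half) {
      for (dc in -half:half) {
        if (dr == 0 && dc == 0) next
        shifted <- matrix(0, nr, nc)
        src_r <- max(1, 1 - dr):min(nr, nr - dr)
        src_c <- max(1, 1 - dc):min(nc, nc - dc)
        shifted[src_r + dr, src_c + dc] <- ind[src_r, src_c]
        acc <- acc + shifted
      }
    }
    out[, , cl] <- acc
  }
  out
}

# Largest-remainder rounding of non-negative reals to integers with an exact
# total.
round_to_total <- function(x, total) {
  f <- floor(x)
  rem <- total - sum(f)
  if (rem > 0) {
    ord <- order(x - f, decreasing = TRUE)
    f[ord[seq_len(rem)]] <- f[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(x - f)
    take <- ord[f[ord] > 0][seq_len(-rem)]
    f[take] <- f[take] - 1
  }
  as.integer(f)
}

#' Spatial allocation of land-use demand by a FLUS-style cellular automaton
#'
#' Iteratively converts pixels until every class's pixel count is within
#' `demand_tolerance` of its demand. Each pixel of an over-supplied class is
#' a conversion candidate; its combined probability for target class j is
#'
#'   suitability_j x (eps + weight_j x neighborhood share of j) x inertia_j
#'   x conversion-cost gate
#'
#' where the self-adaptive inertia of each class rises while its allocation
#' lags demand and falls while it overshoots, and the next class is chosen by
#' a seeded roulette wheel over the allowed targets (classes still in
#' deficit, plus staying put). Conversions into classes at or above demand
#' and cost-forbidden transitions never occur, so total pixel count is
#' conserved and the allocation approaches demand monotonically.
#'
#' @param initial [lu_map()] at the start of the step.
#' @param surface `suitability_surface` aligned with `initial`.
#' @param params [ca_params()].
#' @param demand Named per-class demand in pixels; must total the map's pixel
#'   count within `demand_tolerance` (then rounded to an exact partition).
#' @return An [lu_map()] with attributes `iterations`, `converged`, and
#'   `deficit` (remaining demand minus counts); non-convergence is reported
#'   through `converged = FALSE`, never by silently dropping demand.
#' @export
ca_allocate <- function(initial, surface, params, demand) {
  stopifnot(inherits(initial, "lu_map"), inherits(params, "ca_params"))
  probs <- if (inherits(surface, "suitability_surface")) surface$probs
           else surface
  if (!all(dim(probs)[1:2] == dim(initial$codes))) {
    stop("suitability surface and map are not aligned")
  }
  k <- length(initial$classes)
  n <- length(initial$codes)
  dem <- demand[initial$classes]
  if (anyNA(dem)) stop("demand must be named over all classes")
  if (abs(sum(dem) - n) > params$demand_tolerance * n) {
    stop("demand total (", sum(dem), ") does not match map pixels (", n, ")")
  }
  dem <- round_to_total(pmax(dem, 0) * n / sum(dem), n)
  wts <- params$neighborhood_weights %||% rep(0.5, k)
  cost <- params$conversion_cost %||% matrix(1, k, k)
  cost <- as.matrix(cost)
  diag(cost) <- 1
  suit <- matrix(probs, n, k)
  cur <- as.vector(initial$codes)
  counts <- tabulate(cur, nbins = k)
  inertia <- rep(1, k)
  tol <- params$demand_tolerance
  eps <- 1e-4
  iter <- 0L
  nr <- nrow(initial$codes); nc <- ncol(initial$codes)
  with_local_seed(params$seed, {
    repeat {
      deficit <- dem - counts
      if (all(abs(deficit) <= tol * dem) || iter >= params$max_iterations) break
      iter <- iter + 1L
      # self-adaptive inertia: grows geometrically while a class lags demand,
      # shrinks while it overshoots, so persistent lags eventually dominate
      # the roulette even on low-suitability ground
      inertia <- pmin(pmax(inertia * (1 + params$inertia_step * sign(deficit)),
                           1e-8), 1e8)
      neigh <- matrix(neighborhood_counts(matrix(cur, nr, nc), k,
                                          params$window), n, k) /
        (params$window^2 - 1)
      cand <- which(deficit[cur] < 0)
      cand <- cand[sample.int(length(cand))]
      if (!length(cand)) break
      ci <- cur[cand]
      w <- suit[cand, , drop = FALSE] *
        (eps + sweep(neigh[cand, , drop = FALSE], 2, wts, "*")) *
        rep(inertia, each = length(cand)) *
        cost[ci, , drop = FALSE]
      allow <- matrix(deficit > 0, length(cand), k, byrow = TRUE)
      allow[cbind(seq_along(cand), ci)] <- TRUE    # staying put is allowed
      w[!allow] <- 0
      # roulette wheel, one draw per candidate
      cs <- t(apply(w, 1, cumsum))
      tot <- cs[, k]
      u <- stats::runif(length(cand)) * tot
      pick <- max.col(cs >= u, ties.method = "first")
      pick[tot <= 0] <- ci[tot <= 0]
      # accept conversions in candidate order while demand headroom remains
      for (idx in which(pick != ci)) {
        i <- cand[idx]; from <- ci[idx]; to <- pick[idx]
        if (deficit[from] >= 0 || deficit[to] <= 0) next
        cur[i] <- to
        counts[from] <- counts[from] - 1L; counts[to] <- counts[to] + 1L
        deficit[from] <- deficit[from] + 1L; deficit[to] <- deficit[to] - 1L
      }
    }
  })
  out <- lu_map(matrix(cur, nr, nc), classes = initial$classes,
                pixel_size = initial$pixel_size)
  attr(out, "iterations") <- iter
  attr(out, "converged") <- all(abs(dem - counts) <= tol * dem)
  attr(out, "deficit") <- stats::setNames(dem - counts, initial$classes)
  out
}
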