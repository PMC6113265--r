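#' Train a per-class land-use suitability surface
#'
#' FLUS-style suitability: a single-hidden-layer neural network (softmax
#' output, one unit per class) trained on a uniform random sample of pixels
#' against min-max-normalized driving factors, then evaluated at every pixel.
#' Classes present on the map but under-represented in the uniform sample are
#' topped up to a minimum per-class count; classes absent from the map are
#' excluded from training with a warning and assigned a flat probability
#' before the per-pixel renormalization to sum 1.
#'
#' @param factors 3-D factor array from [generate_driving_factors()] (or any
#'   `[nrow, ncol, n_factors]` array with at least 3 factors).
#' @param landuse Aligned [lu_map()].
#' @param sample_fraction Fraction of pixels sampled for training.
#' @param seed Integer seed (sampling and network initialization).
#' @param hidden Hidden-layer size; default `2 * n_factors`.
#' @param maxit,decay Optimizer iterations and weight decay passed to
#'   [nnet::nnet()].
#' @param min_per_class Minimum training pixels per present class.
#' @return A `suitability_surface`: list with `probs` (array
#'   `[nrow, ncol, n_classes]`, rows summing to 1 per pixel), `classes`, and
#'   `meta` (factors used, sample size, seed).
#' @export
train_suitability <- function(factors, landuse, sample_fraction = 0.05,
                              seed = 1L, hidden = NULL, maxit = 400,
                              decay = 1e-4, min_per_class = 50) {
  stopifnot(length(dim(factors)) == 3)
  nf <- dim(factors)[3]
  if (nf < 3) stop("need at least 3 driving factors")
  if (!all(dim(factors)[1:2] == dim(landuse$codes))) {
    stop("factor stack and land-use map are not aligned")
  }
  cls <- landuse$classes
  k <- length(cls)
  n <- prod(dim(landuse$codes))
  x <- matrix(factors, n, nf)
  colnames(x) <- dimnames(factors)[[3]] %||% paste0("f", seq_len(nf))
  # min-max normalization per factor
  rng <- apply(x, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], .Machine$double.eps)
  x <- sweep(sweep(x, 2, rng[1, ]), 2, span, "/")
  y <- as.vector(landuse$codes)
  present <- sort(unique(y))
  absent <- setdiff(seq_len(k), present)
  if (length(absent)) {
    warning("classes absent from the map, assigned flat suitability: ",
            paste(cls[absent], collapse = ", "))
  }
  probs_flat <- matrix(0, n, k)
  meta <- list(factors = colnames(x), seed = seed,
               sample_fraction = sample_fraction, hidden = hidden)
  with_local_seed(seed, {
    idx <- sample.int(n, max(2, round(sample_fraction * n)))
    for (cl in present) {   # stratified top-up for rare classes
      have <- sum(y[idx] == cl)
      pool <- which(y == cl)
      need <- min(min_per_class, length(pool)) - have
      if (need > 0) {
        idx <- c(idx, sample(pool, need,
                             replace = length(pool) < need))
      }
    }
    meta$sample_size <- length(idx)
    if (length(present) == 1) {
      probs_flat[, present] <- 1
    } else {
      yf <- factor(y[idx], levels = present)
      targets <- nnet::class.ind(yf)
      if (is.null(hidden)) hidden <- 2 * nf
      fit <- nnet::nnet(x[idx, , drop = FALSE], targets, size = hidden,
                        softmax = TRUE, maxit = maxit, decay = decay,
                        trace = FALSE, MaxNWts = 1e5)
      pred <- stats::predict(fit, x)
      probs_flat[, present] <- pred
    }
  })
  if (length(absent)) probs_flat[, absent] <- 1 / k
  probs_flat <- probs_flat / rowSums(probs_flat)
  probs <- array(probs_flat, dim = c(dim(landuse$codes), k),
                 dimnames = list(NULL, NULL, cls))
  structure(list(probs = probs, classes = cls, meta = meta),
            class = "suitability_surface")
}

#' Rank-based ROC AUC of a suitability surface
#'
#' For each class present on the actual map, computes the area under the ROC
#' curve of that class's suitability probabilities against presence/absence,
#' by the Mann-Whitney rank statistic (ties get midranks). AUC 1 means the
#' surface ranks every presence pixel above every absence pixel; 0.5 is
#' chance. Classes absent from the map get `NA`.
#'
#' @param surface A `suitability_surface` from [train_suitability()], or an
#'   array `[nrow, ncol, n_classes]` of probabilities.
#' @param actual Aligned [lu_map()].
#' @return Named numeric vector of per-class AUC values in `[0, 1]`.
#' @export
roc_auc <- function(surface, actual) {
  probs <- if (inherits(surface, "suitability_surface")) surface$probs
           else surface
  stopifnot(length(dim(probs)) == 3)
  if (!all(dim(probs)[1:2] == dim(actual$codes))) {
    stop("surface and map are not aligned")
  }
  k <- dim(probs)[3]
  y <- as.vector(actual$codes)
  out <- stats::setNames(rep(NA_real_, k),
                         actual$classes[seq_len(k)])
  for (cl in seq_len(k)) {
    pos <- y == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) next
    s <- as.vector(probs[, , cl])
    r <- rank(s)
    out[cl] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  out
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the marginals. When `p_e = 1` (both maps
#' constant and equal) kappa is defined as 1.
#'
#' @param cm Square confusion matrix of pixel counts (rows: simulated,
#'   columns: actual).
#' @return Kappa in `[-1, 1]`.
#' @export
kappa_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-12) return(1)
  (po - pe) / (1 - pe)
}

#' Cohen's kappa agreement between two land-use maps
#'
#' @param simulated,actual Aligned [lu_map()]s with the same class set.
#' @return Kappa in `[-1, 1]`.
#' @export
kappa_statistic <- function(simulated, actual) {
  check_aligned(simulated, actual)
  if (!identical(simulated$classes, actual$classes)) {
    stop("maps carry different class sets")
  }
  k <- length(simulated$classes)
  cm <- table(factor(as.vector(simulated$codes), levels = seq_len(k)),
              factor(as.vector(actual$codes), levels = seq_len(k)))
  kappa_from_confusion(matrix(as.numeric(cm), k, k))
}
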