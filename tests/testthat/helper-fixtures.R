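# Shared fixtures: built in code, small enough to regenerate per file.

# 2-class transition matrix with labels a/b.
tm2 <- function(p11, p12, p21, p22, period = 1) {
  transition_matrix(matrix(c(p11, p12, p21, p22), 2, byrow = TRUE),
                    classes = c("a", "b"), period_years = period)
}

# A small landscape bundle cached across tests in one session.
small_bundle <- local({
  cache <- NULL
  function(seed = 42, n = 60) {
    key <- paste(seed, n)
    if (is.null(cache) || !identical(attr(cache, "key"), key)) {
      b <- generate_landscape(synthetic_config(n, n, seed = seed))
      attr(b, "key") <- key
      cache <<- b
    }
    cache
  }
})

# Uniform random row-stochastic matrix over the six classes.
random_stochastic <- function(seed) {
  set.seed(seed)
  p <- matrix(stats::runif(36), 6, 6)
  p <- p / rowSums(p)
  transition_matrix(p, classes = mods_classes(), period_years = 1)
}
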