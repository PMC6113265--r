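digit_mats <- function(tuples) {
  # tuples: matrix n x 6 of digits; returns named list of 1 x n matrices
  setNames(lapply(seq_len(6), function(j) matrix(tuples[, j], 1)), es_order())
}

test_that("min-max normalization: span, degeneracy, order preservation", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(5, 5, 5)), c(0, 0, 0))
  x <- c(3, -1, 7, 2, 2.5)
  expect_equal(rank(minmax_normalize(x)), rank(x))
  # idempotence on an already [0,1]-spanning series
  y <- c(0, 0.3, 1, 0.6)
  expect_equal(minmax_normalize(y), y)
  expect_error(minmax_normalize(c(1, NaN)), "finite")
  expect_error(minmax_normalize(3), "length")
})

test_that("regional trend classification and pairwise interactions", {
  series <- list(WY = c(100, 95, 90, 85), SC = c(10, 12, 14, 16),
                 CP = c(5, 6, 7, 8), CS = c(50, 55, 60, 65),
                 SF = c(20, 20.02, 20.04, 20.06),  # +0.3% total
                 AV = c(7, 7, 7, 7))
  out <- classify_regional_trends(series, unchanged_threshold = 0.01)
  expect_equal(unname(out$trend[c("WY", "SC", "CP", "SF", "AV")]),
               c("decrease", "increase", "increase", "unchanged",
                 "unchanged"))
  expect_equal(out$pairs["WY", "SC"], "trade-off")
  expect_equal(out$pairs["CP", "CS"], "synergy")
  expect_true(all(out$pairs["SF", c("WY", "SC", "CP", "CS")] == "neutral"))
  # symmetry
  expect_identical(out$pairs, t(out$pairs))

  # wild swings are excluded as mixed, with a warning
  series$CP <- c(5, 50, 2, 8)
  expect_warning(out2 <- classify_regional_trends(series), "mixed")
  expect_equal(unname(out2$trend["CP"]), "mixed")
  expect_true(all(is.na(out2$pairs["CP", ])))
})

test_that("per-pixel reclassification honours the epsilon band", {
  mk <- function(v) es_layer(matrix(v, 1, 1), "WY", units = "mm")
  expect_equal(reclass_change(mk(0), mk(10), epsilon = 0)[1, 1], 1L)
  expect_equal(reclass_change(mk(5), mk(5), epsilon = 0)[1, 1], 3L)
  expect_equal(reclass_change(mk(0), mk(-0.5), epsilon = 1)[1, 1], 3L)
  expect_equal(reclass_change(mk(0), mk(-0.5), epsilon = 0.1)[1, 1], 2L)
  wrong <- es_layer(matrix(1, 1, 1), "WY", units = "t km-2")
  expect_error(reclass_change(mk(0), wrong), "unit mismatch")
})

test_that("encode/decode is a bijection over all 729 codes", {
  tuples <- as.matrix(expand.grid(rep(list(1:3), 6)))[, 6:1]
  codes <- encode_overlay(digit_mats(tuples), pixel_size = 100)
  expect_equal(length(unique(as.vector(codes$codes))), 729)
  for (i in seq_len(729)) {
    dec <- decode_code(codes$codes[1, i])
    redig <- integer(6)
    names(redig) <- es_order()
    redig[dec$increases] <- 1L
    redig[dec$decreases] <- 2L
    redig[redig == 0L] <- 3L
    expect_equal(unname(redig), unname(tuples[i, ]))
  }
  expect_equal(encode_overlay(digit_mats(matrix(c(1, 1, 1, 1, 2, 2), 1)))
               $codes[1, 1], "111122")
  expect_error(encode_overlay(digit_mats(matrix(c(1, 4, 1, 1, 2, 2), 1))),
               "\\{1, 2, 3\\}")
})

test_that("decoded labels follow the figure-legend convention", {
  # WY=2, CP=1, SC=1, SF=2, CS=1, AV=1
  dec <- decode_code("211211")
  expect_equal(dec$label, "SC+ CP+ CS+ AV+, WY- SF-")
  expect_true(dec$synergy_increase && dec$synergy_decrease && dec$trade_off)
  expect_equal(decode_code("333333")$label, "no change")
  one <- decode_code("333133")
  expect_false(one$synergy_increase || one$synergy_decrease || one$trade_off)
  expect_error(decode_code("12345"), "malformed")
  expect_error(decode_code("111114"), "malformed")
})

test_that("area filter keeps codes strictly over the threshold", {
  # 100 m pixels: 4000 pixels = 40 km2 exactly (dropped), 4001 retained
  n <- 4000 + 4001
  codes_vec <- c(rep("111122", 4000), rep("211211", 4001))
  codes <- structure(list(codes = matrix(codes_vec, 1, n),
                          es_order = es_order(), pixel_size = 100,
                          legend = NULL),
                     class = "interaction_codes")
  out <- filter_codes_by_area(codes, min_area_km2 = 40)
  leg <- out$legend
  expect_false(leg$retained[leg$code == "111122"])
  expect_true(leg$retained[leg$code == "211211"])
  # legend sorted by area descending
  expect_equal(leg$code, c("211211", "111122"))
  # relabeling conserves pixels
  expect_equal(sum(out$classes == "other interactions"), 4000)
  expect_equal(length(out$classes), n)
  # a vanishing threshold retains every non-empty code
  out0 <- filter_codes_by_area(codes, min_area_km2 = 1e-9)
  expect_true(all(out0$legend$retained))
  expect_error(filter_codes_by_area(codes, min_area_km2 = 0), "positive")
})

test_that("cause attribution cross-tab is marginally consistent", {
  # all "111122" pixels sit on bare -> cropland transitions
  n <- 100
  codes_vec <- c(rep("111122", 40), rep("333333", 60))
  codes <- structure(list(codes = matrix(codes_vec, 1, n),
                          es_order = es_order(), pixel_size = 100,
                          legend = NULL),
                     class = "interaction_codes")
  t0 <- lu_map(matrix(c(rep(6L, 40), rep(3L, 60)), 1, n))
  t1 <- lu_map(matrix(c(rep(1L, 40), rep(3L, 60)), 1, n))
  out <- attribute_causes(codes, t0, t1)
  dom <- out$dominant
  expect_equal(dom$transition[dom$interaction == "111122"],
               "bare -> cropland")
  expect_equal(dom$pct[dom$interaction == "111122"], 100)
  # row sums equal per-class pixel counts
  sums <- tapply(out$table$n, out$table$interaction, sum)
  expect_equal(as.vector(sums[c("111122", "333333")]), c(40, 60))

  # unchanged land use everywhere: every class dominated by "no transition"
  out2 <- attribute_causes(codes, t0, t0)
  expect_true(all(out2$dominant$transition == "no transition"))
})

test_that("grid digits of a uniformly increasing service match its regional trend", {
  # every pixel digit 1 for an ES <=> its regional series increases
  t0 <- es_layer(matrix(1, 5, 5), "CS", units = "kg")
  t1 <- es_layer(matrix(2, 5, 5), "CS", units = "kg")
  expect_true(all(reclass_change(t0, t1) == 1L))
  series <- c(sum(t0$values), sum(t1$values))
  expect_gt(series[2], series[1])
})
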