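test_that("transition estimation matches hand cross-tabulation", {
  t0 <- lu_map(matrix(c(1L, 1L, 1L, 2L), 2, 2, byrow = TRUE),
               classes = c("a", "b"))
  t1 <- lu_map(matrix(c(1L, 2L, 1L, 2L), 2, 2, byrow = TRUE),
               classes = c("a", "b"))
  est <- estimate_transition_matrix(t0, t1)
  expect_equal(est$probs["a", "a"], 2 / 3)
  expect_equal(est$probs["a", "b"], 1 / 3)
  expect_equal(est$probs["b", "b"], 1)

  # identical maps give the identity matrix
  expect_equal(estimate_transition_matrix(t0, t0)$probs,
               diag(2), ignore_attr = TRUE)

  # a class absent at t0 gets an identity row, no division error
  t0b <- lu_map(matrix(1L, 2, 2), classes = c("a", "b"))
  est2 <- estimate_transition_matrix(t0b, t0b)
  expect_equal(unname(est2$probs["b", ]), c(0, 1))

  expect_error(estimate_transition_matrix(
    t0, lu_map(matrix(1L, 3, 3), classes = c("a", "b"))), "grid mismatch")
})

test_that("parameter recovery from simulated pairs at 1e5 pixels", {
  gen <- random_stochastic(17)
  pair <- generate_markov_pair(gen, 1e5, seed = 18)
  est <- estimate_transition_matrix(pair$map_t0, pair$map_t1)
  expect_lt(max(abs(est$probs - gen$probs)), 0.02)
})

test_that("scenario modifiers scale targeted entries and renormalize", {
  tm <- transition_matrix(matrix(c(0.8, 0.1, 0.1,
                                   0, 1, 0,
                                   0, 0, 1), 3, byrow = TRUE),
                          classes = c("stay", "crop", "built"))
  ed <- scenario_spec("ED", data.frame(
    from = c("stay", "stay"), to = c("crop", "built"),
    change = c(0.5, 2.0)))
  out <- apply_scenario_modifiers(tm, ed)
  expect_equal(unname(out$probs["stay", ]), c(0.55, 0.15, 0.30))
  expect_equal(rowSums(out$probs), rep(1, 3), ignore_attr = TRUE)

  # BAU: empty modifier list leaves the matrix unchanged
  expect_equal(apply_scenario_modifiers(tm, scenario_spec("BAU"))$probs,
               tm$probs)

  # -100% zeroes the entry and the diagonal absorbs the residual
  tm2c <- transition_matrix(matrix(c(0.9, 0.04, 0.06,
                                     0, 1, 0,
                                     0, 0, 1), 3, byrow = TRUE),
                            classes = c("forest", "cropland", "x"))
  ec <- scenario_spec("EC", data.frame(from = "forest", to = "cropland",
                                       change = -1))
  out2 <- apply_scenario_modifiers(tm2c, ec)
  expect_equal(out2$probs["forest", "cropland"], 0)
  expect_equal(out2$probs["forest", "forest"], 0.94)

  expect_error(scenario_spec("X", data.frame(from = "a", to = "b",
                                             change = -1.2)), "-1")
  expect_error(scenario_spec("X", data.frame(from = "a", to = "a",
                                             change = 0.5)), "off-diagonal")
})

test_that("modifier renormalization keeps rows stochastic, incl. fallback", {
  for (s in 1:5) {
    tm <- random_stochastic(s)
    big <- scenario_spec("big", data.frame(
      from = "bare", to = c("cropland", "built"), change = c(8, 8)))
    out <- apply_scenario_modifiers(tm, big)
    expect_equal(rowSums(out$probs), rep(1, 6), ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_true(all(out$probs >= 0))
    # targeted relative change preserved exactly when no fallback triggers
    off <- sum(out$probs["bare", ]) - out$probs["bare", "bare"]
    if (out$probs["bare", "bare"] > 0) {
      expect_equal(out$probs["bare", "cropland"],
                   9 * tm$probs["bare", "cropland"])
    } else {
      expect_equal(off, 1, tolerance = 1e-12)
    }
  }
})

test_that("matrix step-splitting returns an n-th root", {
  id <- transition_matrix(diag(3), classes = c("a", "b", "c"))
  expect_equal(step_split_matrix(id, 4)$probs, diag(3), ignore_attr = TRUE)

  p <- tm2(0.9, 0.1, 0.05, 0.95, period = 10)
  q <- step_split_matrix(p, 2)
  expect_lt(sqrt(sum((q$probs %*% q$probs - p$probs)^2)), 1e-8)
  expect_equal(q$period_years, 5)
  expect_false(attr(q, "meta")$regularized)

  expect_identical(step_split_matrix(p, 1), p)

  # a matrix without a clean stochastic root falls back to regularization
  hard <- transition_matrix(matrix(c(0, 1, 1, 0), 2), classes = c("a", "b"))
  qh <- step_split_matrix(hard, 2)
  expect_true(attr(qh, "meta")$regularized)
  expect_equal(rowSums(qh$probs), c(1, 1), ignore_attr = TRUE)
})

test_that("demand projection follows a_{t+1} = a_t P and conserves mass", {
  id <- transition_matrix(diag(2), classes = c("a", "b"))
  traj <- project_demand(id, c(a = 10, b = 20), 2015:2020)
  expect_true(all(traj$a == 10 & traj$b == 20))

  p <- tm2(0.5, 0.5, 0, 1)
  traj2 <- project_demand(p, c(a = 100, b = 0), 0:2)
  expect_equal(unname(as.matrix(traj2[, c("a", "b")])),
               matrix(c(100, 0, 50, 50, 25, 75), 3, byrow = TRUE))

  for (s in 1:5) {
    tm <- random_stochastic(s)
    a0 <- setNames(runif(6, 0, 100), mods_classes())
    tr <- project_demand(tm, a0, 0:5)
    sums <- rowSums(as.matrix(tr[, -1]))
    expect_equal(sums, rep(sum(a0), 6), ignore_attr = TRUE,
                 tolerance = 1e-6 * sum(a0))
    expect_true(all(as.matrix(tr[, -1]) >= 0))
  }

  expect_error(project_demand(p, c(a = -1, b = 2), 0:1), "non-negative")
  expect_error(project_demand(p, c(a = 1, b = 2), c(0, 2)), "spacing")
})

test_that("monotone scenario effect: ED demand for cropland/built >= BAU", {
  est <- default_calibration_matrix(15)
  scen <- default_scenarios()
  areas <- setNames(c(130, 260, 1250, 40, 25, 1880), mods_classes())
  years <- seq(2015, 2035, by = 15)
  bau <- project_demand(apply_scenario_modifiers(est, scen$BAU), areas, years)
  ed <- project_demand(apply_scenario_modifiers(est, scen$ED), areas, years)
  expect_true(all(ed$cropland >= bau$cropland))
  expect_true(all(ed$built >= bau$built))
})
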