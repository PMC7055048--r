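test_that("transition matrices are row-stochastic with the documented structure", {
  p <- eurofit_params()
  for (arm in c("eurofit", "control")) {
    tm <- transition_matrix(p, arm)
    expect_true(all(abs(rowSums(tm) - 1) <= 1e-12))
    expect_true(all(tm >= 0 & tm <= 1))
    # death absorbing
    expect_equal(unname(tm["dead", ]), c(rep(0, 8), 1))
    # disease rows: mass only on self and death, no recovery
    for (d in dis_states) {
      expect_equal(tm[d, d], 1 - p$disease_mortality[[d]])
      expect_equal(tm[d, "dead"], p$disease_mortality[[d]])
      expect_equal(sum(tm[d, setdiff(all_states, c(d, "dead"))]), 0)
    }
    # disease entries verbatim from the incidence table
    expect_equal(tm[act_states, dis_states], p$disease_incidence,
                 ignore_attr = TRUE)
  }
})

test_that("activity rows are rescaled by the conditional factor", {
  p <- eurofit_params()
  tm <- transition_matrix(p, "eurofit")
  # hand arithmetic over the published inactive row: disease + death mass
  exit <- 0.015 + 0.011 + 0.005 + 0.0046 + 0.010 + 0.016
  expect_equal(exit, 0.0616)
  raw <- c(4 / 21, 0.34 / 6.04, 59.4 / 79) # unrounded trial proportions
  f <- (1 - exit) / sum(raw)
  expect_equal(unname(tm["inactive", act_states]), raw * f)
  expect_equal(unname(attr(tm, "renorm_factors")["inactive"]), f)

  # stroke row from the published mortality value
  expect_equal(tm["stroke", "stroke"], 0.600)
  expect_equal(tm["stroke", "dead"], 0.400)

  # with all exits zeroed and a row already stochastic, the factor is ~1
  p0 <- eurofit_params(overrides = zero_exit_overrides())
  tm0 <- transition_matrix(p0, "eurofit")
  raw_sum <- sum(raw)
  expect_equal(unname(attr(tm0, "renorm_factors")["inactive"]), 1 / raw_sum)
  expect_equal(sum(tm0["inactive", act_states]), 1)

  # exit mass >= 1 cannot be represented
  p_bad <- eurofit_params()
  p_bad$activity_mortality["inactive"] <- 0.97
  expect_error(transition_matrix(p_bad, "eurofit"), "no mass")
})

test_that("cohort trace conserves mass and death is monotone", {
  p <- eurofit_params()
  for (arm in c("eurofit", "control")) {
    tr <- run_cohort(p, arm)
    expect_equal(dim(tr), c(6, 9))
    expect_equal(unname(tr[1, ]), c(1750, 1050, 7200, rep(0, 6)))
    expect_true(all(abs(rowSums(tr) - 10000) <= 1e-6))
    expect_true(all(tr >= 0))
    expect_true(all(diff(tr[, "dead"]) >= 0))
  }
})

test_that("no exits means nobody dies", {
  p0 <- eurofit_params(overrides = zero_exit_overrides())
  tr <- run_cohort(p0, "eurofit")
  expect_equal(unname(tr[, "dead"]), rep(0, 6))
  expect_equal(unname(tr[, "stroke"]), rep(0, 6))
})

test_that("raising a disease mortality never lowers final deaths", {
  p <- eurofit_params()
  base_dead <- run_cohort(p, "control")[6, "dead"]
  for (d in dis_states) {
    key <- paste("disease_mortality", d, sep = ".")
    bumped <- eurofit_params(overrides = setNames(
      list(min(1, p$disease_mortality[[d]] + 0.2)), key))
    expect_gte(run_cohort(bumped, "control")[6, "dead"], base_dead)
  }
})

test_that("intervention effect duration switches the eurofit matrix", {
  # with effect over the full horizon the matrix is identical at every cycle
  p <- eurofit_params()
  t1 <- transition_matrix(p, "eurofit", cycle = 1)
  for (cy in 2:5)
    expect_equal(transition_matrix(p, "eurofit", cycle = cy), t1)

  # with a 1-year effect, cycle 2+ uses the control matrix
  p1 <- eurofit_params(overrides = list(effect_duration_years = 1))
  expect_equal(unclass(transition_matrix(p1, "eurofit", cycle = 1)),
               unclass(t1), ignore_attr = TRUE)
  expect_equal(unclass(transition_matrix(p1, "eurofit", cycle = 2)),
               unclass(transition_matrix(p1, "control", cycle = 2)),
               ignore_attr = TRUE)

  # the cohort does not jump at the switch: cycle-1 occupancy matches the
  # full-effect run, later cycles drift toward the control mix
  tr_full <- run_cohort(p, "eurofit")
  tr_1y <- run_cohort(p1, "eurofit")
  expect_equal(tr_1y[2, ], tr_full[2, ])
  expect_false(isTRUE(all.equal(tr_1y[3, ], tr_full[3, ])))
})

test_that("cohort trace equals the microsimulation expectation", {
  # marginally, microsimulated occupancy at cycle t is multinomial around
  # the cohort-trace proportions, so per-cell z-scores should look
  # standard normal. With 96 free cells a per-cell 3-sigma check fails by
  # multiplicity alone, so agreement is asserted familywise: no cell
  # beyond 4 sigma, and at most 5% of cells beyond 3 sigma.
  p <- eurofit_params()
  n <- 1e6
  set.seed(2611)
  for (arm in c("eurofit", "control")) {
    ms <- microsim_trace(p, arm, n)
    trace <- run_cohort(p, arm)
    prop <- unclass(trace) / p$cohort_size
    se <- sqrt(prop * (1 - prop) / n)
    free <- se > 0
    z <- abs(ms / n - prop)[free] / se[free]
    expect_lt(max(z), 4)
    expect_lte(mean(z > 3), 0.05)
    # structurally empty cells are exactly empty in the microsimulation
    expect_equal(unname((ms / n)[!free]), unname(prop[!free]))
    expect_true(all(rowSums(ms) == n))
  }
})
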