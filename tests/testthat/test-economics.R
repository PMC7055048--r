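test_that("discount factors follow the closed form", {
  expect_equal(discount_factor(1, 0.035), 1 / 1.035)
  expect_equal(discount_factor(1, 0.035), 0.966184, tolerance = 1e-6)
  expect_equal(discount_factor(5, 0.035), 1.035^-5)
  expect_equal(discount_factor(5, 0.035), 0.841973, tolerance = 1e-6)
  expect_equal(discount_factor(3, 0), 1)
  expect_equal(discount_factor(0, 0.05), 1)
  expect_error(discount_factor(1, -0.1), ">= 0")
})

test_that("payoff accumulation matches a brute-force oracle", {
  for (spec in list(c("societal", "trial"), c("healthcare", "literature"))) {
    p <- eurofit_params(spec[1], spec[2])
    for (arm in c("eurofit", "control")) {
      trace <- run_cohort(p, arm)
      got <- accumulate_payoffs(trace, p, arm)
      u <- eurofitce:::active_utilities(p)
      cc <- eurofitce:::active_costs(p)
      want <- oracle_payoffs(trace, u, cc, p$discount_rate_costs,
                             p$discount_rate_effects,
                             program = if (arm == "eurofit")
                               p$program_cost * p$cohort_size else 0)
      expect_equal(got$total_cost, want$total_cost)
      expect_equal(got$total_qalys, want$total_qalys)
    }
  }
})

test_that("degenerate cohorts give closed-form payoffs", {
  # everyone stays in a utility-1, cost-0 state: undiscounted QALYs = 5N
  p <- eurofit_params(overrides = c(
    zero_exit_overrides(),
    list(discount_rate_costs = 0, discount_rate_effects = 0,
         initial_activity = c(inactive = 0, moderate = 0, recommended = 1),
         "utilities.trial.recommended.value" = 1,
         "annual_costs.societal.recommended.value" = 0,
         # keep all mass in the recommended state
         "activity_transitions.eurofit.recommended.recommended.value" = 1,
         "activity_transitions.eurofit.recommended.inactive.value" = 0,
         "activity_transitions.eurofit.recommended.moderate.value" = 0,
         "activity_transitions.control.recommended.recommended.value" = 1,
         "activity_transitions.control.recommended.inactive.value" = 0,
         "activity_transitions.control.recommended.moderate.value" = 0)
  ))
  ctl <- accumulate_payoffs(run_cohort(p, "control"), p, "control")
  expect_equal(ctl$total_qalys, 5 * 10000)
  expect_equal(ctl$total_cost, 0)

  # the eurofit arm adds only the one-off programme cost: 260 x 10,000
  eur <- accumulate_payoffs(run_cohort(p, "eurofit"), p, "eurofit")
  expect_equal(eur$total_cost, 2600000)

  # with discounting, total QALYs are the cohort times a geometric sum
  # over the first-year-undiscounted convention
  r <- 0.035
  pd <- eurofit_params(overrides = c(
    zero_exit_overrides(),
    list(initial_activity = c(inactive = 0, moderate = 0, recommended = 1),
         "utilities.trial.recommended.value" = 1,
         "activity_transitions.control.recommended.recommended.value" = 1,
         "activity_transitions.control.recommended.inactive.value" = 0,
         "activity_transitions.control.recommended.moderate.value" = 0)
  ))
  got <- accumulate_payoffs(run_cohort(pd, "control"), pd, "control")
  expect_equal(got$total_qalys, 10000 * sum((1 + r)^-(0:4)))
  # discounting can only shrink positive payoffs
  expect_lt(got$total_qalys, 5 * 10000)
})

test_that("QALY totals are invariant under state relabelling", {
  # swapping the utility values of two states while swapping their
  # occupancies (via the initial distribution) leaves totals unchanged
  p1 <- eurofit_params(overrides = c(zero_exit_overrides(), list(
    initial_activity = c(inactive = 0.3, moderate = 0.7, recommended = 0),
    "utilities.trial.inactive.value" = 0.5,
    "utilities.trial.moderate.value" = 0.9,
    "activity_transitions.control.inactive.inactive.value" = 1,
    "activity_transitions.control.inactive.moderate.value" = 0,
    "activity_transitions.control.inactive.recommended.value" = 0,
    "activity_transitions.control.moderate.moderate.value" = 1,
    "activity_transitions.control.moderate.inactive.value" = 0,
    "activity_transitions.control.moderate.recommended.value" = 0)))
  p2 <- eurofit_params(overrides = c(zero_exit_overrides(), list(
    initial_activity = c(inactive = 0.7, moderate = 0.3, recommended = 0),
    "utilities.trial.inactive.value" = 0.9,
    "utilities.trial.moderate.value" = 0.5,
    "activity_transitions.control.inactive.inactive.value" = 1,
    "activity_transitions.control.inactive.moderate.value" = 0,
    "activity_transitions.control.inactive.recommended.value" = 0,
    "activity_transitions.control.moderate.moderate.value" = 1,
    "activity_transitions.control.moderate.inactive.value" = 0,
    "activity_transitions.control.moderate.recommended.value" = 0)))
  q1 <- accumulate_payoffs(run_cohort(p1, "control"), p1, "control")$total_qalys
  q2 <- accumulate_payoffs(run_cohort(p2, "control"), p2, "control")$total_qalys
  expect_equal(q1, q2)
})

test_that("ICER arithmetic and verdicts cover all four quadrants", {
  mk <- function(dc, de) compare_arms(
    list(total_cost = 1e6 + dc, total_qalys = 1e4 + de),
    list(total_cost = 1e6, total_qalys = 1e4), cohort_size = 1e4)

  ne <- mk(100000, 10)
  expect_equal(ne$icer, 10000)
  expect_equal(ne$verdict, "icer")

  # published one-year-effect style division: the printed incremental
  # QALYs are rounded, the ICER must come from the unrounded value
  expect_equal(mk(654611, 125.74)$icer, 654611 / 125.74)
  expect_equal(round(mk(654611, 125.74)$icer), 5206)

  dom <- mk(-2595287, 373)
  expect_equal(dom$verdict, "dominant")
  expect_lt(dom$icer, 0)

  expect_equal(mk(500, -2)$verdict, "dominated")
  expect_equal(mk(-500, -2)$verdict, "icer_southwest")
  expect_equal(mk(-500, -2)$icer, 250)

  zero <- mk(500, 0)
  expect_equal(zero$verdict, "no_qaly_difference")
  expect_true(is.na(zero$icer))

  # bookkeeping: increments and per-person columns
  expect_equal(ne$incremental_cost, 100000)
  expect_equal(ne$incremental_qalys, 10)
  expect_equal(unname(ne$per_person_cost["eurofit"]), (1e6 + 1e5) / 1e4)
})

test_that("zero discounting weakly dominates discounted totals", {
  p <- eurofit_params()
  p0 <- eurofit_params(overrides = list(discount_rate_costs = 0,
                                        discount_rate_effects = 0))
  for (arm in c("eurofit", "control")) {
    d <- accumulate_payoffs(run_cohort(p, arm), p, arm)
    u <- accumulate_payoffs(run_cohort(p0, arm), p0, arm)
    expect_gte(u$total_cost, d$total_cost)
    expect_gte(u$total_qalys, d$total_qalys)
  }
})
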