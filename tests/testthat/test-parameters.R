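test_that("packaged fixture matches the published parameter manifest", {
  manifest <- read.csv(system.file("extdata", "parameter_manifest.csv",
                                   package = "eurofitce"))
  flat <- flatten_parameters(eurofit_params())
  # every manifest entry appears exactly once, with the published value
  for (i in seq_len(nrow(manifest))) {
    hit <- flat[flat$block == manifest$block[i] & flat$key == manifest$key[i], ]
    expect_equal(nrow(hit), 1,
                 info = paste(manifest$block[i], manifest$key[i]))
    expect_equal(hit$printed, manifest$printed[i],
                 info = paste(manifest$block[i], manifest$key[i]))
  }
  # and nothing beyond the manifest
  expect_equal(nrow(flat), nrow(manifest))
})

test_that("fixture exposes the documented base-case values", {
  p <- eurofit_params()
  flat <- flatten_parameters(p)
  get <- function(block, key) flat[flat$block == block & flat$key == key, ]

  expect_equal(get("utility.trial", "inactive")$printed, 0.909)
  expect_equal(get("annual_cost.societal", "inactive")$printed, 2436)
  expect_equal(get("program_cost", "eurofit_program")$value, 260)
  expect_equal(p$initial_activity,
               c(inactive = 0.175, moderate = 0.105, recommended = 0.720))
  expect_equal(p$cohort_size, 10000)
  expect_equal(p$horizon_years, 5L)
  expect_equal(p$discount_rate_costs, 0.035)

  hc <- eurofit_params("healthcare")
  expect_equal(flatten_parameters(hc)[
    flatten_parameters(hc)$block == "annual_cost.healthcare" &
      flatten_parameters(hc)$key == "inactive", ]$printed, 1107)
  lit <- eurofit_params(utility_source = "literature")
  expect_equal(get("utility.literature", "recommended")$printed, 0.91)
})

test_that("activity-transition working values are the beta means", {
  p <- eurofit_params()
  tr <- p$activity_transitions
  i <- tr$arm == "eurofit" & tr$from == "inactive" & tr$to == "inactive"
  expect_equal(tr$value[i], 4.0 / (4.0 + 17.0))
  expect_equal(tr$printed[i], 0.18)
  # each arm's rows of working values sum close to 1 (unrounded trial
  # proportions), while the printed values do not
  for (arm in c("eurofit", "control")) for (from in act_states) {
    s <- tr[tr$arm == arm & tr$from == from, ]
    expect_lt(abs(sum(s$value) - 1), 0.01)
  }
})

test_that("overrides change single fields and invalid values are rejected", {
  p10 <- eurofit_params(overrides = list(horizon_years = 10))
  p <- eurofit_params()
  expect_equal(p10$horizon_years, 10L)
  p10$horizon_years <- p$horizon_years
  expect_equal(p10, p)

  expect_error(
    eurofit_params(overrides = list("utilities.condition.stroke.value" = 1.3)),
    "utilities.condition.stroke"
  )
  expect_error(eurofit_params(overrides = list(no_such_key = 1)),
               "unknown override")
  expect_error(
    eurofit_params(overrides = list("activity_transitions.eurofit.inactive.dead.value" = 0.5)),
    "no such"
  )
  expect_error(load_parameters(tempfile(fileext = ".yaml")), "not found")
})

test_that("validation names the offending parameter", {
  expect_error(
    eurofit_params(overrides = list("disease_mortality.stroke" = 1.4)),
    "disease_mortality"
  )
  expect_error(
    eurofit_params(overrides = list(
      initial_activity = c(inactive = 0.5, moderate = 0.5, recommended = 0.5))),
    "sum to 1"
  )
  expect_error(
    eurofit_params(overrides = list("annual_costs.societal.stroke.value" = -5)),
    "annual_costs.societal.stroke"
  )
  # exit mass >= 1 from an activity state is a model-specification error
  expect_error(
    eurofit_params(overrides = list("activity_mortality.inactive" = 0.99)),
    "must be < 1"
  )
})

test_that("write-then-load round trip is exact", {
  p <- eurofit_params("healthcare", "literature",
                      overrides = list(horizon_years = 7))
  # perturb some values to non-terminating decimals
  set.seed(99)
  p2 <- sample_parameters(p)
  f <- tempfile(fileext = ".yaml")
  write_parameters(p2, f)
  p3 <- load_parameters(f)
  expect_identical(p3$activity_transitions$value, p2$activity_transitions$value)
  expect_identical(p3$utilities$value, p2$utilities$value)
  expect_identical(p3$annual_costs$value, p2$annual_costs$value)
  expect_equal(p3, p2)
})

test_that("dist_spec enforces family-specific bounds", {
  expect_error(dist_spec("beta", -1, 2, value = 0.5), "shape1")
  expect_error(dist_spec("beta", 1, 2, value = 1.5), "\\[0, 1\\]")
  expect_error(dist_spec("gamma", 1, 2, value = -1), ">= 0")
  expect_equal(dist_mean(dist_spec("beta", 4, 17, value = 0.18)), 4 / 21)
  expect_equal(dist_mean(dist_spec("gamma", 0.19, 12658, value = 2436)),
               0.19 * 12658)
  expect_equal(dist_mean(dist_spec("fixed", value = 0.4)), 0.4)
})

test_that("the state space is nine states in three categories", {
  hs <- health_states()
  expect_equal(nrow(hs), 9)
  expect_equal(sum(hs$category == "activity"), 3)
  expect_equal(sum(hs$category == "disease"), 5)
  expect_equal(hs$state[hs$category == "absorbing"], "dead")
})
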