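#' Scenario specification
#'
#' A named set of parameter overrides relative to the base case. Only
#' the analysis-level settings that define the published scenarios can
#' be overridden here: time horizon, costing perspective, utility
#' source, duration of the intervention effect, and the two discount
#' rates. The base case is the empty override set.
#'
#' @param name Scenario label.
#' @param overrides Named list; allowed keys are `horizon_years`,
#'   `perspective`, `utility_source`, `effect_duration_years`,
#'   `discount_rate_costs`, `discount_rate_effects`.
#' @return A `scenario_spec` object.
#' @export
#' @examples
#' scenario_spec("horizon_10y", list(horizon_years = 10))
scenario_spec <- function(name, overrides = list()) {
  allowed <- c("horizon_years", "perspective", "utility_source",
               "effect_duration_years", "discount_rate_costs",
               "discount_rate_effects")
  bad <- setdiff(names(overrides), allowed)
  if (length(bad))
    stop("scenario '", name, "': unknown override key(s): ",
         paste(bad, collapse = ", "))
  structure(list(name = name, overrides = overrides), class = "scenario_spec")
}

#' The published scenario set
#'
#' The base case plus the four scenario analyses: extending the horizon
#' to 10 years (with the intervention effect maintained throughout),
#' the healthcare costing perspective, activity-state utilities from the
#' literature, and an intervention effect limited to the first year
#' (control transitions for the EuroFIT arm from cycle 2 onward).
#'
#' @return Named list of [scenario_spec()] objects.
#' @export
canonical_scenarios <- function() {
  list(
    base = scenario_spec("base", list()),
    horizon_10y = scenario_spec("horizon_10y", list(horizon_years = 10)),
    healthcare = scenario_spec("healthcare", list(perspective = "healthcare")),
    literature_utilities = scenario_spec("literature_utilities",
                                         list(utility_source = "literature")),
    effect_1y = scenario_spec("effect_1y", list(effect_duration_years = 1))
  )
}

#' Discount-rate sensitivity grid
#'
#' The deterministic sensitivity analyses on discounting: rates of 0%
#' and 5% applied to costs only, effects only, and both simultaneously
#' (base case: 3.5% on both).
#'
#' @return Named list of [scenario_spec()] objects.
#' @export
discount_scenarios <- function() {
  specs <- list()
  for (r in c(0, 0.05)) {
    tag <- sprintf("%g", 100 * r)
    specs[[paste0("discount_costs_", tag)]] <-
      scenario_spec(paste0("discount_costs_", tag),
                    list(discount_rate_costs = r))
    specs[[paste0("discount_effects_", tag)]] <-
      scenario_spec(paste0("discount_effects_", tag),
                    list(discount_rate_effects = r))
    specs[[paste0("discount_both_", tag)]] <-
      scenario_spec(paste0("discount_both_", tag),
                    list(discount_rate_costs = r, discount_rate_effects = r))
  }
  specs
}

apply_scenario <- function(base, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  validate_parameters(apply_overrides(base, spec$overrides))
}

#' Run one deterministic scenario
#'
#' Applies the scenario overrides to the base parameters and runs the
#' deterministic model for both arms.
#'
#' @param base A `ce_params` object (the base case).
#' @param spec A [scenario_spec()].
#' @return A `ce_result`.
#' @export
run_scenario <- function(base, spec) {
  run_ce(apply_scenario(base, spec))
}

#' Tornado table of scenario impacts on the ICER
#'
#' Runs each scenario deterministically and reports the ICER point
#' estimate and its percent change against the base-case ICER. Dominant
#' scenarios (cost-saving with QALY gain) carry a negative ICER and are
#' flagged rather than hidden, so a dominant outcome appears as a large
#' negative percent change.
#'
#' @param base A `ce_params` object.
#' @param specs List of [scenario_spec()] objects; defaults to the
#'   published scenarios plus the discount-rate grid.
#' @return A data.frame with columns `name`, `icer`, `dominant`,
#'   `pct_change_vs_base`.
#' @export
tornado <- function(base, specs = c(canonical_scenarios()[-1],
                                    discount_scenarios())) {
  base_res <- run_ce(base)
  if (!is.finite(base_res$icer))
    stop("tornado requires a finite base-case ICER")
  rows <- lapply(specs, function(spec) {
    res <- run_scenario(base, spec)
    data.frame(name = spec$name, icer = res$icer,
               dominant = identical(res$verdict, "dominant"),
               pct_change_vs_base =
                 100 * (res$icer - base_res$icer) / abs(base_res$icer))
  })
  out <- do.call(rbind, c(list(data.frame(name = "base", icer = base_res$icer,
                                          dominant = FALSE,
                                          pct_change_vs_base = 0)), rows))
  rownames(out) <- NULL
  out
}

#' Probabilistic sensitivity analysis for a scenario
#'
#' Applies the scenario overrides, runs the full PSA and returns the
#' acceptability curve together with the underlying draws.
#'
#' @param base A `ce_params` object.
#' @param spec A [scenario_spec()].
#' @param n_sims,seed Passed to [run_psa()].
#' @param thresholds Passed to [compute_ceac()].
#' @return A list with `spec`, `psa` (a `ce_psa`) and `ceac`.
#' @export
run_scenario_psa <- function(base, spec, n_sims = 25000, seed = 1,
                             thresholds = ceac_thresholds()) {
  psa <- run_psa(apply_scenario(base, spec), n_sims = n_sims, seed = seed)
  list(spec = spec, psa = psa, ceac = compute_ceac(psa, thresholds))
}
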