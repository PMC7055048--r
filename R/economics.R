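#' Discount factor
#'
#' `(1 + rate)^(-cycle)`. The model's accounting convention (see
#' [accumulate_payoffs()]) discounts payoffs accrued during cycle `t`
#' with exponent `t - 1`, i.e. the first model year is not discounted.
#'
#' @param cycle Non-negative exponent (years into the future).
#' @param rate Annual discount rate.
#' @return Numeric discount factor(s).
#' @export
#' @examples
#' discount_factor(1, 0.035) # 0.966184
#' discount_factor(5, 0.035) # 0.841973
discount_factor <- function(cycle, rate) {
  if (any(rate < 0)) stop("discount rate must be >= 0")
  (1 + rate)^(-cycle)
}

#' Discounted costs and QALYs for one cohort trace
#'
#' Person-years spent in state `s` during cycle `t` are taken as the
#' occupancy at the end of cycle `t` (no half-cycle correction). QALYs
#' accrue as occupancy times the state utility; costs as occupancy times
#' the annual state cost. Payoffs of cycle `t` are discounted with
#' exponent `t - 1`: the first model year is undiscounted, matching the
#' published cohort totals. For the EuroFIT arm the one-off programme
#' cost (`program_cost` per participant) is added undiscounted at
#' enrolment. The dead state accrues zero cost and zero utility.
#'
#' @param trace A `ce_trace` from [run_cohort()].
#' @param params The `ce_params` the trace was produced under.
#' @param arm `"eurofit"` or `"control"`.
#' @return A list with `total_cost` (euro) and `total_qalys` (QALYs) for
#'   the whole cohort.
#' @export
accumulate_payoffs <- function(trace, params, arm = .arms) {
  arm <- match.arg(arm)
  h <- params$horizon_years
  if (nrow(trace) != h + 1)
    stop("trace has ", nrow(trace) - 1, " cycles but horizon is ", h)
  u <- active_utilities(params)
  cc <- active_costs(params)
  t_seq <- seq_len(h)
  df_e <- discount_factor(t_seq - 1, params$discount_rate_effects)
  df_c <- discount_factor(t_seq - 1, params$discount_rate_costs)
  occ <- unclass(trace)[t_seq + 1, , drop = FALSE]
  total_qalys <- sum((occ %*% u) * df_e)
  total_cost <- sum((occ %*% cc) * df_c)
  if (arm == "eurofit")
    total_cost <- total_cost + params$program_cost * params$cohort_size
  list(total_cost = total_cost, total_qalys = total_qalys)
}

#' Incremental cost-effectiveness comparison of the two arms
#'
#' Combines per-arm discounted totals into the incremental
#' cost-effectiveness result: incremental cost and QALYs
#' (EuroFIT minus control), the ICER where it is defined, and the
#' cost-effectiveness-plane verdict. `"icer"` (north-east: more costly,
#' more effective, ICER = delta cost / delta QALYs), `"dominant"`
#' (cheaper and more effective), `"dominated"` (more costly, less
#' effective), `"icer_southwest"` (cheaper and less effective; the ratio
#' is reported but reads as savings per QALY forgone), or
#' `"no_qaly_difference"` when delta QALYs is 0.
#'
#' @param result_eurofit,result_control Lists with `total_cost` and
#'   `total_qalys`, as returned by [accumulate_payoffs()].
#' @param cohort_size Persons per arm, for the per-person columns.
#' @return A `ce_result` object.
#' @export
compare_arms <- function(result_eurofit, result_control, cohort_size) {
  dc <- result_eurofit$total_cost - result_control$total_cost
  de <- result_eurofit$total_qalys - result_control$total_qalys
  if (de == 0) {
    verdict <- "no_qaly_difference"
    icer <- NA_real_
  } else {
    icer <- dc / de
    verdict <- if (dc >= 0 && de > 0) "icer"
      else if (dc < 0 && de > 0) "dominant"
      else if (dc >= 0 && de < 0) "dominated"
      else "icer_southwest"
  }
  structure(list(
    total_cost = c(eurofit = result_eurofit$total_cost,
                   control = result_control$total_cost),
    total_qalys = c(eurofit = result_eurofit$total_qalys,
                    control = result_control$total_qalys),
    incremental_cost = dc,
    incremental_qalys = de,
    icer = icer,
    verdict = verdict,
    per_person_cost = c(eurofit = result_eurofit$total_cost,
                        control = result_control$total_cost) / cohort_size,
    per_person_qalys = c(eurofit = result_eurofit$total_qalys,
                         control = result_control$total_qalys) / cohort_size,
    cohort_size = cohort_size
  ), class = "ce_result")
}

#' Deterministic cost-effectiveness analysis
#'
#' Runs both arms of the model under one parameter set and returns the
#' incremental comparison: the deterministic counterpart of one PSA
#' draw, and the base-case analysis when called on [eurofit_params()].
#'
#' @param params A `ce_params` object.
#' @return A `ce_result` object.
#' @export
#' @examples
#' run_ce(eurofit_params())
run_ce <- function(params) {
  res <- lapply(stats::setNames(.arms, .arms), function(arm)
    accumulate_payoffs(run_cohort(params, arm), params, arm))
  compare_arms(res$eurofit, res$control, params$cohort_size)
}

#' @export
print.ce_result <- function(x, ...) {
  eur <- function(v) formatC(v, format = "f", digits = 0, big.mark = ",")
  cat("<ce_result> EuroFIT vs no intervention\n")
  cat(sprintf("  total cost   : %s vs %s (delta %s)\n",
              eur(x$total_cost[["eurofit"]]), eur(x$total_cost[["control"]]),
              eur(x$incremental_cost)))
  cat(sprintf("  total QALYs  : %s vs %s (delta %.1f)\n",
              eur(x$total_qalys[["eurofit"]]), eur(x$total_qalys[["control"]]),
              x$incremental_qalys))
  cat(sprintf("  per person   : %s vs %s euro; %.3f vs %.3f QALYs\n",
              eur(x$per_person_cost[["eurofit"]]),
              eur(x$per_person_cost[["control"]]),
              x$per_person_qalys[["eurofit"]], x$per_person_qalys[["control"]]))
  v <- switch(x$verdict,
    icer = sprintf("ICER %s euro/QALY", eur(x$icer)),
    dominant = sprintf("dominant (ICER %s euro/QALY)", eur(x$icer)),
    dominated = "dominated",
    icer_southwest = sprintf("cheaper and less effective (%s euro/QALY)",
                             eur(x$icer)),
    no_qaly_difference = "no QALY difference; ICER undefined"
  )
  cat("  verdict      :", v, "\n")
  invisible(x)
}

#' One-row summary of a cost-effectiveness result
#'
#' @param result A `ce_result`.
#' @param analysis Label for the first column.
#' @return A one-row data.frame mirroring the published results layout
#'   (total costs and QALYs per arm, increments, ICER, verdict).
#' @export
ce_row <- function(result, analysis = "base_case") {
  data.frame(
    analysis = analysis,
    cost_eurofit = result$total_cost[["eurofit"]],
    cost_control = result$total_cost[["control"]],
    qalys_eurofit = result$total_qalys[["eurofit"]],
    qalys_control = result$total_qalys[["control"]],
    incremental_cost = result$incremental_cost,
    incremental_qalys = result$incremental_qalys,
    icer = result$icer,
    verdict = result$verdict
  )
}
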