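#' Draw one parameter set for probabilistic sensitivity analysis
#'
#' Replaces the working value of every non-fixed parameter by a draw
#' from its PSA distribution: beta for the activity transitions (per
#' arm, independently), beta for the activity-state utilities and gamma
#' for the activity-state annual costs. Literature-sourced parameters
#' (disease incidence, all mortality, disease utilities and costs, the
#' programme cost) are fixed and pass through unchanged. Utilities and
#' costs are drawn once per call and shared by both arms; only the
#' active utility source and costing perspective are sampled.
#'
#' Uses the current RNG state; seed management lives in [run_psa()].
#' The draw order is fixed (EuroFIT transitions, control transitions,
#' utilities, costs, each in canonical state order), so a given RNG
#' state always yields the same parameter set.
#'
#' @param params A `ce_params` object.
#' @return A `ce_params` object with sampled working values.
#' @export
sample_parameters <- function(params) {
  params$activity_transitions <- sample_param_table(params$activity_transitions)

  ut <- params$utilities
  act_src <- if (params$utility_source == "trial") "trial" else "literature"
  b <- which(ut$source == act_src & ut$family == "beta")
  if (length(b))
    ut$value[b] <- stats::rbeta(length(b), ut$shape1[b], ut$shape2[b])
  params$utilities <- ut

  co <- params$annual_costs
  g <- which(co$perspective == params$perspective & co$family == "gamma")
  if (length(g))
    co$value[g] <- stats::rgamma(length(g), shape = co$shape1[g],
                                 scale = co$shape2[g])
  params$annual_costs <- co
  params
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: for each simulation
#' a parameter set is drawn with [sample_parameters()], the transition
#' matrices are rebuilt (sampled activity rows are renormalised exactly
#' as in the deterministic engine), both arms are run, and the
#' incremental cost and QALYs are recorded.
#'
#' Reproducibility: each draw runs on its own substream seed derived
#' deterministically from `seed`, so results are bit-reproducible and
#' the first `k` draws do not depend on `n_sims`.
#'
#' @param params A `ce_params` object.
#' @param n_sims Number of Monte Carlo simulations (25,000 in the
#'   published analysis).
#' @param seed Integer root seed.
#' @return A `ce_psa` object: a list with `draws` (data.frame with one
#'   row per simulation: per-arm discounted totals, `delta_cost`,
#'   `delta_qalys`), `n_sims`, `seed`, and the deterministic
#'   `base_result`.
#' @export
run_psa <- function(params, n_sims = 25000, seed = 1) {
  stopifnot(n_sims >= 1)
  set.seed(seed)
  draw_seeds <- as.integer(floor(stats::runif(n_sims) * 2147483646)) + 1L

  cost_e <- cost_c <- qaly_e <- qaly_c <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    set.seed(draw_seeds[i])
    sp <- sample_parameters(params)
    res <- tryCatch(run_ce(sp), error = function(e)
      stop("PSA draw ", i, " failed: ", conditionMessage(e), call. = FALSE))
    cost_e[i] <- res$total_cost[["eurofit"]]
    cost_c[i] <- res$total_cost[["control"]]
    qaly_e[i] <- res$total_qalys[["eurofit"]]
    qaly_c[i] <- res$total_qalys[["control"]]
  }
  structure(list(
    draws = data.frame(
      cost_eurofit = cost_e, cost_control = cost_c,
      qalys_eurofit = qaly_e, qalys_control = qaly_c,
      delta_cost = cost_e - cost_c, delta_qalys = qaly_e - qaly_c
    ),
    n_sims = n_sims, seed = seed,
    base_result = run_ce(params)
  ), class = "ce_psa")
}

#' Empirical credibility interval
#'
#' Central credibility interval from the empirical percentiles of the
#' draws (2.5% and 97.5% for the default 95% level), using
#' linear interpolation between order statistics (R quantile type 7).
#'
#' @param draws Numeric vector of PSA draws.
#' @param level Interval mass, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' credibility_interval(1:1000) # c(25.975, 975.025)
credibility_interval <- function(draws, level = 0.95) {
  stopifnot(length(draws) >= 1, level > 0, level < 1)
  q <- stats::quantile(draws, c((1 - level) / 2, (1 + level) / 2),
                       names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Default willingness-to-pay grid for acceptability curves
#'
#' 0 to 50,000 euro per QALY in steps of 1,000, covering the 10,000 /
#' 22,000 / 34,000 euro thresholds discussed with the results (the NICE
#' range of 20,000--30,000 pounds corresponds to 22,000--34,000 euro).
#'
#' @return Numeric vector of thresholds (euro per QALY).
#' @export
ceac_thresholds <- function() seq(0, 50000, by = 1000)

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold `lambda`, the probability that
#' EuroFIT is cost-effective: the fraction of PSA draws with positive
#' incremental net monetary benefit, `lambda * dQALY - dCost > 0`. At
#' `lambda = 0` this is the fraction of draws in which EuroFIT saves
#' money.
#'
#' @param psa A `ce_psa` object (or a data.frame with `delta_cost` and
#'   `delta_qalys` columns).
#' @param thresholds Willingness-to-pay grid, euro per QALY.
#' @return A data.frame (class `ce_ceac`) with columns `threshold` and
#'   `probability`.
#' @export
compute_ceac <- function(psa, thresholds = ceac_thresholds()) {
  stopifnot(all(thresholds >= 0))
  draws <- if (inherits(psa, "ce_psa")) psa$draws else psa
  prob <- vapply(thresholds, function(lambda)
    mean(lambda * draws$delta_qalys - draws$delta_cost > 0), numeric(1))
  structure(data.frame(threshold = thresholds, probability = prob),
            class = c("ce_ceac", "data.frame"))
}

#' @export
summary.ce_psa <- function(object, level = 0.95, ...) {
  d <- object$draws
  ci_c <- credibility_interval(d$delta_cost, level)
  ci_q <- credibility_interval(d$delta_qalys, level)
  out <- data.frame(
    quantity = c("incremental_cost", "incremental_qalys"),
    mean = c(mean(d$delta_cost), mean(d$delta_qalys)),
    lower = c(ci_c[["lower"]], ci_q[["lower"]]),
    upper = c(ci_c[["upper"]], ci_q[["upper"]])
  )
  attr(out, "level") <- level
  attr(out, "n_sims") <- object$n_sims
  out
}

#' @export
print.ce_psa <- function(x, ...) {
  cat(sprintf("<ce_psa> %s Monte Carlo simulations (seed %d)\n",
              format(x$n_sims, big.mark = ","), x$seed))
  s <- summary(x)
  cat(sprintf("  incremental cost : mean %s, 95%% CrI (%s; %s)\n",
              formatC(s$mean[1], format = "f", digits = 0, big.mark = ","),
              formatC(s$lower[1], format = "f", digits = 0, big.mark = ","),
              formatC(s$upper[1], format = "f", digits = 0, big.mark = ",")))
  cat(sprintf("  incremental QALYs: mean %.1f, 95%% CrI (%.1f; %.1f)\n",
              s$mean[2], s$lower[2], s$upper[2]))
  invisible(x)
}
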