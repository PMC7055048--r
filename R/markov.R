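#' Annual transition matrix for one arm
#'
#' Assembles the 9 x 9 row-stochastic annual transition matrix. For each
#' activity state the annual disease-incidence and mortality
#' probabilities are entered verbatim, and the three activity-to-activity
#' probabilities (raw trial estimates, which need not sum exactly to the
#' remaining mass) are rescaled by a common factor
#' `(1 - incidence - mortality) / sum(activity row)` so that the row sums
#' to exactly 1. This makes the observed activity transitions conditional
#' on neither falling ill nor dying during the cycle. Disease states can
#' only be left through death (stay-probability `1 - mortality`); death
#' is absorbing.
#'
#' If `cycle > params$effect_duration_years` the EuroFIT arm uses the
#' control arm's activity transitions: the intervention effect has worn
#' off and the matrix, not the cohort, changes.
#'
#' @param params A `ce_params` object.
#' @param arm `"eurofit"` or `"control"`.
#' @param cycle Cycle index (1-based) the matrix applies to.
#' @return A 9 x 9 matrix with state dimnames, `arm` and the three
#'   row-renormalisation factors attached as attributes.
#' @export
#' @examples
#' T1 <- transition_matrix(eurofit_params(), "eurofit")
#' rowSums(T1)
transition_matrix <- function(params, arm = .arms, cycle = 1) {
  arm <- match.arg(arm)
  if (cycle < 1) stop("cycle must be >= 1")
  eff_arm <- if (arm == "eurofit" && cycle > params$effect_duration_years)
    "control" else arm
  act <- activity_matrix(params, eff_arm)

  m <- matrix(0, 9, 9, dimnames = list(.states, .states))
  factors <- numeric(3)
  for (i in seq_along(.activity_states)) {
    a <- .activity_states[i]
    exit <- sum(params$disease_incidence[a, ]) + params$activity_mortality[[a]]
    avail <- 1 - exit
    if (avail <= 0)
      stop("disease incidence plus mortality from '", a, "' leaves no mass ",
           "for activity transitions")
    row_sum <- sum(act[a, ])
    if (row_sum <= 0)
      stop("activity transition row from '", a, "' sums to 0")
    factors[i] <- avail / row_sum
    m[a, .activity_states] <- act[a, ] * factors[i]
    m[a, .disease_states] <- params$disease_incidence[a, ]
    m[a, "dead"] <- params$activity_mortality[[a]]
  }
  for (d in .disease_states) {
    m[d, d] <- 1 - params$disease_mortality[[d]]
    m[d, "dead"] <- params$disease_mortality[[d]]
  }
  m["dead", "dead"] <- 1
  structure(m, arm = arm,
            renorm_factors = stats::setNames(factors, .activity_states))
}

#' Propagate the cohort over the model horizon
#'
#' Distributes the cohort over the three activity states according to
#' the initial activity distribution and multiplies it through the
#' annual transition matrix for each cycle. The transition matrix is
#' constant over time except for the EuroFIT arm when the intervention
#' effect is limited to fewer years than the horizon, in which case the
#' control matrix applies from the first post-effect cycle onward.
#'
#' @param params A `ce_params` object.
#' @param arm `"eurofit"` or `"control"`.
#' @return A `(horizon + 1) x 9` occupancy matrix (persons per state at
#'   each cycle boundary; row `"0"` is the initial distribution), class
#'   `ce_trace`, with `arm` and `cohort_size` attributes.
#' @export
run_cohort <- function(params, arm = .arms) {
  arm <- match.arg(arm)
  h <- params$horizon_years
  occ <- matrix(0, h + 1, 9, dimnames = list(0:h, .states))
  occ[1, .activity_states] <- params$cohort_size * params$initial_activity

  m <- transition_matrix(params, arm, cycle = 1)
  for (t in seq_len(h)) {
    if (t > 1 && arm == "eurofit" &&
        (t - 1) <= params$effect_duration_years &&
        t > params$effect_duration_years)
      m <- transition_matrix(params, arm, cycle = t)
    occ[t + 1, ] <- occ[t, ] %*% m
  }
  structure(occ, arm = arm, cohort_size = params$cohort_size,
            class = c("ce_trace", class(occ)))
}

#' @export
print.ce_trace <- function(x, ...) {
  cat(sprintf("<ce_trace> arm '%s', cohort %s, %d cycles\n",
              attr(x, "arm"), format(attr(x, "cohort_size"), big.mark = ","),
              nrow(x) - 1))
  print(round(unclass(x), 1))
  invisible(x)
}
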