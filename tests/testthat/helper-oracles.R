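# Shared helpers: independent oracles and degenerate parameter builders.

act_states <- c("inactive", "moderate", "recommended")
dis_states <- c("colorectal_cancer", "chd", "t2d", "stroke", "depression")
all_states <- c(act_states, dis_states, "dead")

# Overrides that remove every exit from the activity states
# (no disease, no death).
zero_exit_overrides <- function() {
  ov <- list()
  for (a in act_states) {
    for (d in dis_states)
      ov[[paste("disease_incidence", a, d, sep = ".")]] <- 0
    ov[[paste("activity_mortality", a, sep = ".")]] <- 0
  }
  ov
}

# Overrides that turn every sampled parameter into a fixed one (value kept),
# so the PSA degenerates to the deterministic analysis.
all_fixed_overrides <- function() {
  ov <- list()
  for (arm in c("eurofit", "control")) for (f in act_states) for (t in act_states)
    ov[[paste("activity_transitions", arm, f, t, "family", sep = ".")]] <- "fixed"
  for (s in act_states) {
    ov[[paste("utilities", "trial", s, "family", sep = ".")]] <- "fixed"
    ov[[paste("annual_costs", "societal", s, "family", sep = ".")]] <- "fixed"
    ov[[paste("annual_costs", "healthcare", s, "family", sep = ".")]] <- "fixed"
  }
  ov
}

# Independent individual-level microsimulation with the same transition
# matrices: per cycle and state, destination counts are multinomial.
# Starts from the deterministic initial occupancy so that the only noise
# is transition sampling.
microsim_trace <- function(params, arm, n) {
  h <- params$horizon_years
  occ <- matrix(0, h + 1, 9, dimnames = list(0:h, all_states))
  occ[1, act_states] <- round(n * params$initial_activity)
  for (t in seq_len(h)) {
    tm <- transition_matrix(params, arm, t)
    nxt <- numeric(9)
    for (s in 1:9) {
      if (occ[t, s] > 0)
        nxt <- nxt + drop(stats::rmultinom(1, occ[t, s], tm[s, ]))
    }
    occ[t + 1, ] <- nxt
  }
  occ
}

# Brute-force payoff accumulation: explicit scalar loops over cycles and
# states, independent of the package's matrix arithmetic.
oracle_payoffs <- function(trace, utilities, costs, rate_costs, rate_effects,
                           program = 0) {
  utilities <- unname(utilities)
  costs <- unname(costs)
  q <- 0
  cs <- program
  for (t in seq_len(nrow(trace) - 1)) {
    for (s in seq_len(ncol(trace))) {
      q <- q + trace[t + 1, s] * utilities[s] * (1 + rate_effects)^(-(t - 1))
      cs <- cs + trace[t + 1, s] * costs[s] * (1 + rate_costs)^(-(t - 1))
    }
  }
  list(total_cost = cs, total_qalys = q)
}
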