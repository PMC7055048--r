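#' Load model parameters from a configuration file
#'
#' Reads a structured-text (YAML) model configuration, applies optional
#' overrides, validates every invariant and returns a `ce_params` object.
#' The configuration holds the complete parameter set: per-arm activity
#' transitions with their PSA beta distributions, fixed annual disease
#' incidence and mortality, utilities from both sources (trial EQ-5D-5L
#' and literature), annual costs for both costing perspectives, and the
#' one-off programme cost.
#'
#' Deterministic working values: parameters estimated from the trial
#' carry a published two-figure value and a PSA distribution whose
#' parameters encode the unrounded estimate. For activity transitions the
#' working value is the beta mean (the exact trial proportion; each row
#' of beta means sums to ~1, unlike the independently rounded published
#' values); utilities and costs use the published value. An explicit
#' `value` field in the configuration takes precedence, which makes
#' [write_parameters()] / [load_parameters()] round-trips exact.
#'
#' @param path Path to a YAML configuration file.
#' @param overrides Named list of overrides. Top-level fields
#'   (`horizon_years`, `discount_rate_costs`, `discount_rate_effects`,
#'   `effect_duration_years`, `cohort_size`, `perspective`,
#'   `utility_source`, `program_cost`, `initial_activity`) are named
#'   directly; individual table cells use dotted paths such as
#'   `"utilities.condition.stroke.value"` or
#'   `"activity_transitions.eurofit.inactive.recommended.value"`.
#' @return A validated `ce_params` object.
#' @seealso [eurofit_params()] for the packaged parameter set,
#'   [write_parameters()] for the inverse operation.
#' @export
load_parameters <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  cfg <- yaml::read_yaml(path)

  known <- c("model", "analysis", "activity_transitions", "disease_incidence",
             "activity_mortality", "disease_mortality", "utilities",
             "annual_costs", "program_cost")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown configuration section(s): ", paste(extra, collapse = ", "))
  missing <- setdiff(known, names(cfg))
  if (length(missing))
    stop("configuration section(s) missing: ", paste(missing, collapse = ", "))

  m <- cfg$model
  eff <- m$effect_duration_years
  if (identical(eff, "horizon")) eff <- Inf

  params <- structure(list(
    cohort_size = as.numeric(m$cohort_size),
    horizon_years = as.integer(m$horizon_years),
    cycle_length_years = as.numeric(m$cycle_length_years),
    discount_rate_costs = as.numeric(m$discount_rate_costs),
    discount_rate_effects = as.numeric(m$discount_rate_effects),
    effect_duration_years = as.numeric(eff),
    initial_activity = unlist(m$initial_activity)[.activity_states],
    perspective = cfg$analysis$perspective,
    utility_source = cfg$analysis$utility_source,
    activity_transitions = parse_transition_block(cfg$activity_transitions),
    disease_incidence = parse_incidence(cfg$disease_incidence),
    activity_mortality = unlist(cfg$activity_mortality)[.activity_states],
    disease_mortality = unlist(cfg$disease_mortality)[.disease_states],
    utilities = parse_payoff_block(cfg$utilities, "source",
                                   c("trial", "literature", "condition")),
    annual_costs = parse_payoff_block(cfg$annual_costs, "perspective",
                                      c("societal", "healthcare")),
    program_cost = as.numeric(cfg$program_cost)
  ), class = "ce_params")

  params <- apply_overrides(params, overrides)
  validate_parameters(params)
}

#' The packaged EuroFIT parameter set
#'
#' Returns the full published parameter set of the EuroFIT
#' cost-effectiveness model for a given costing perspective and utility
#' source. `societal` + `trial` is the base case: societal costs
#' (healthcare plus productivity losses, euro 2017), EQ-5D-5L utilities
#' measured in the trial, 5-year horizon, 3.5% annual discounting, cohort
#' of 10,000 per arm, and an intervention effect maintained over the full
#' horizon.
#'
#' @param perspective `"societal"` (base case) or `"healthcare"`.
#' @param utility_source `"trial"` (base case) or `"literature"` (0.80 /
#'   0.87 / 0.91 for the three activity levels).
#' @param overrides Passed on to [load_parameters()].
#' @return A validated `ce_params` object.
#' @export
#' @examples
#' p <- eurofit_params()
#' p$initial_activity
eurofit_params <- function(perspective = c("societal", "healthcare"),
                           utility_source = c("trial", "literature"),
                           overrides = list()) {
  perspective <- match.arg(perspective)
  utility_source <- match.arg(utility_source)
  path <- system.file("extdata", "eurofit_params.yaml", package = "eurofitce")
  load_parameters(path, overrides = c(
    list(perspective = perspective, utility_source = utility_source),
    overrides
  ))
}

#' Write model parameters to a configuration file
#'
#' Serialises a `ce_params` object back to the YAML configuration format
#' read by [load_parameters()]. Numeric values are written with enough
#' significant digits to reproduce every double bit-exactly, so a
#' write-then-load round trip yields an identical parameter set.
#'
#' @param params A `ce_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  tr <- params$activity_transitions
  ut <- params$utilities
  co <- params$annual_costs

  row_list <- function(tab, label_cols) {
    lapply(seq_len(nrow(tab)), function(i) {
      r <- as.list(tab[i, c(label_cols, "printed", "value")])
      r$dist <- tab$family[i]
      if (tab$family[i] == "beta") {
        r$alpha <- tab$shape1[i]; r$beta <- tab$shape2[i]
      } else if (tab$family[i] == "gamma") {
        r$shape <- tab$shape1[i]; r$scale <- tab$shape2[i]
      }
      r
    })
  }
  split_by <- function(tab, col, label_cols) {
    out <- lapply(split(tab, tab[[col]])[unique(tab[[col]])],
                  row_list, label_cols = label_cols)
    out
  }

  eff <- params$effect_duration_years
  cfg <- list(
    model = list(
      cohort_size = params$cohort_size,
      horizon_years = params$horizon_years,
      cycle_length_years = params$cycle_length_years,
      discount_rate_costs = params$discount_rate_costs,
      discount_rate_effects = params$discount_rate_effects,
      effect_duration_years = if (is.infinite(eff)) "horizon" else eff,
      initial_activity = as.list(params$initial_activity)
    ),
    analysis = list(perspective = params$perspective,
                    utility_source = params$utility_source),
    activity_transitions = split_by(tr, "arm", c("from", "to")),
    disease_incidence = lapply(.activity_states, function(a)
      as.list(params$disease_incidence[a, ])),
    activity_mortality = as.list(params$activity_mortality),
    disease_mortality = as.list(params$disease_mortality),
    utilities = split_by(ut, "source", "state"),
    annual_costs = split_by(co, "perspective", "state"),
    program_cost = params$program_cost
  )
  names(cfg$disease_incidence) <- .activity_states
  writeLines(yaml::as.yaml(cfg, precision = 20), path)
  invisible(path)
}

#' Validate a model parameter set
#'
#' Checks every structural invariant of the parameter set and fails with
#' an error naming the offending parameter: probabilities and utilities
#' in \[0, 1\], costs non-negative, initial activity distribution summing
#' to 1, published activity rows summing to at most 1.05 (the raw trial
#' estimates need not sum to exactly 1; the transition-matrix builder
#' renormalises them), and per activity state a combined annual disease
#' incidence plus mortality below 1.
#'
#' @param params A `ce_params` object.
#' @return `params`, invisibly, if valid.
#' @export
validate_parameters <- function(params) {
  chk <- function(ok, what, ...) if (!ok) stop("invalid parameter: ",
                                               sprintf(what, ...), call. = FALSE)
  p <- params
  chk(is.finite(p$cohort_size) && p$cohort_size > 0, "cohort_size must be > 0")
  chk(is.finite(p$horizon_years) && p$horizon_years >= 1,
      "horizon_years must be >= 1")
  chk(identical(as.numeric(p$cycle_length_years), 1),
      "cycle_length_years must be 1")
  for (f in c("discount_rate_costs", "discount_rate_effects"))
    chk(p[[f]] >= 0 && p[[f]] <= 1, "%s must lie in [0, 1]", f)
  chk(p$effect_duration_years >= 1, "effect_duration_years must be >= 1")
  chk(all(names(p$initial_activity) == .activity_states) &&
        all(p$initial_activity >= 0),
      "initial_activity must cover the three activity states")
  chk(abs(sum(p$initial_activity) - 1) <= 1e-9,
      "initial_activity must sum to 1 (got %.10f)", sum(p$initial_activity))
  chk(p$perspective %in% c("societal", "healthcare"),
      "perspective '%s' unknown", p$perspective)
  chk(p$utility_source %in% c("trial", "literature"),
      "utility_source '%s' unknown", p$utility_source)

  tr <- p$activity_transitions
  chk(nrow(tr) == 18 && all(table(tr$arm) == 9),
      "activity_transitions must hold 9 entries per arm")
  for (i in seq_len(nrow(tr))) {
    lab <- sprintf("activity_transitions.%s.%s.%s", tr$arm[i], tr$from[i], tr$to[i])
    for (col in c("printed", "value"))
      chk(tr[[col]][i] >= 0 && tr[[col]][i] <= 1, "%s.%s must lie in [0, 1]",
          lab, col)
    if (tr$family[i] != "fixed")
      chk(tr$shape1[i] > 0 && tr$shape2[i] > 0,
          "%s distribution parameters must be > 0", lab)
  }
  for (arm in .arms) for (from in .activity_states) {
    s <- tr[tr$arm == arm & tr$from == from, ]
    chk(nrow(s) == 3, "activity_transitions.%s.%s must have 3 entries", arm, from)
    # the published point estimates are raw trial proportions; they need
    # not sum to exactly 1 but must be close. Working values are allowed
    # to drift further (PSA draws are independent betas that the engine
    # renormalises), so only the per-entry [0, 1] bound applies to them.
    chk(sum(s$printed) > 0 && sum(s$printed) <= 1.05,
        "activity_transitions.%s.%s printed row sum %.4f outside (0, 1.05]",
        arm, from, sum(s$printed))
    chk(sum(s$value) > 0, "activity_transitions.%s.%s value row sums to 0",
        arm, from)
  }

  chk(all(dim(p$disease_incidence) == c(3, 5)),
      "disease_incidence must be 3 x 5")
  chk(all(p$disease_incidence >= 0 & p$disease_incidence <= 1),
      "disease_incidence probabilities must lie in [0, 1]")
  chk(all(p$activity_mortality >= 0 & p$activity_mortality <= 1),
      "activity_mortality probabilities must lie in [0, 1]")
  chk(all(p$disease_mortality >= 0 & p$disease_mortality <= 1),
      "disease_mortality probabilities must lie in [0, 1]")
  exits <- rowSums(p$disease_incidence) + p$activity_mortality
  for (a in .activity_states)
    chk(exits[[a]] < 1,
        "disease incidence plus mortality from '%s' must be < 1", a)

  ut <- p$utilities
  for (i in seq_len(nrow(ut)))
    chk(ut$value[i] >= 0 && ut$value[i] <= 1, "utilities.%s.%s must lie in [0, 1]",
        ut$source[i], ut$state[i])
  co <- p$annual_costs
  for (i in seq_len(nrow(co)))
    chk(co$value[i] >= 0, "annual_costs.%s.%s must be >= 0",
        co$perspective[i], co$state[i])
  chk(p$program_cost >= 0, "program_cost must be >= 0")
  invisible(params)
}

#' Flatten a parameter set to a table
#'
#' One row per model input parameter (69 in the packaged set), with the
#' published value, the deterministic working value and the PSA
#' distribution. Suitable for CSV export and for auditing the parameter
#' set against its source.
#'
#' @param params A `ce_params` object.
#' @return A data.frame with columns `block`, `key`, `printed`, `value`,
#'   `family`, `shape1`, `shape2`.
#' @export
flatten_parameters <- function(params) {
  tr <- params$activity_transitions
  ut <- params$utilities
  co <- params$annual_costs
  inc <- params$disease_incidence
  rows <- rbind(
    data.frame(block = paste0("activity_transition.", tr$arm),
               key = paste0(tr$from, "->", tr$to),
               printed = tr$printed, value = tr$value, family = tr$family,
               shape1 = tr$shape1, shape2 = tr$shape2),
    data.frame(block = "disease_incidence",
               key = paste0(rep(rownames(inc), each = ncol(inc)), "->",
                            rep(colnames(inc), times = nrow(inc))),
               printed = as.vector(t(inc)), value = as.vector(t(inc)),
               family = "fixed", shape1 = NA_real_, shape2 = NA_real_),
    data.frame(block = "activity_mortality", key = .activity_states,
               printed = unname(params$activity_mortality),
               value = unname(params$activity_mortality),
               family = "fixed", shape1 = NA_real_, shape2 = NA_real_),
    data.frame(block = "disease_mortality", key = .disease_states,
               printed = unname(params$disease_mortality),
               value = unname(params$disease_mortality),
               family = "fixed", shape1 = NA_real_, shape2 = NA_real_),
    data.frame(block = paste0("utility.", ut$source), key = ut$state,
               printed = ut$printed, value = ut$value, family = ut$family,
               shape1 = ut$shape1, shape2 = ut$shape2),
    data.frame(block = paste0("annual_cost.", co$perspective), key = co$state,
               printed = co$printed, value = co$value, family = co$family,
               shape1 = co$shape1, shape2 = co$shape2),
    data.frame(block = "program_cost", key = "eurofit_program",
               printed = params$program_cost, value = params$program_cost,
               family = "fixed", shape1 = NA_real_, shape2 = NA_real_)
  )
  rownames(rows) <- NULL
  rows
}

#' @export
print.ce_params <- function(x, ...) {
  eff <- if (is.infinite(x$effect_duration_years)) "full horizon"
         else paste(x$effect_duration_years, "year(s)")
  cat("<ce_params> EuroFIT cost-effectiveness model parameters\n")
  cat(sprintf("  cohort %s per arm, horizon %d y, discounting %.1f%% / %.1f%%\n",
              format(x$cohort_size, big.mark = ","), x$horizon_years,
              100 * x$discount_rate_costs, 100 * x$discount_rate_effects))
  cat(sprintf("  perspective: %s, utilities: %s, intervention effect: %s\n",
              x$perspective, x$utility_source, eff))
  cat(sprintf("  initial activity: %s\n",
              paste(sprintf("%s %.1f%%", names(x$initial_activity),
                            100 * x$initial_activity), collapse = ", ")))
  invisible(x)
}

# ---- internal parsing helpers -------------------------------------------

parse_entry_dist <- function(e, where) {
  fam <- e$dist
  if (is.null(fam)) stop("missing dist family in ", where)
  if (!fam %in% c("beta", "gamma", "fixed"))
    stop("unknown dist family '", fam, "' in ", where)
  s1 <- switch(fam, beta = e$alpha, gamma = e$shape, fixed = NA_real_)
  s2 <- switch(fam, beta = e$beta, gamma = e$scale, fixed = NA_real_)
  list(family = fam, shape1 = as.numeric(s1), shape2 = as.numeric(s2))
}

parse_transition_block <- function(block) {
  if (!setequal(names(block), .arms))
    stop("activity_transitions must have blocks 'eurofit' and 'control'")
  rows <- do.call(rbind, lapply(.arms, function(arm) {
    do.call(rbind, lapply(block[[arm]], function(e) {
      d <- parse_entry_dist(e, sprintf("activity_transitions.%s.%s.%s",
                                       arm, e$from, e$to))
      value <- if (!is.null(e$value)) as.numeric(e$value)
               else if (d$family == "beta") d$shape1 / (d$shape1 + d$shape2)
               else as.numeric(e$printed)
      data.frame(arm = arm, from = e$from, to = e$to, family = d$family,
                 shape1 = d$shape1, shape2 = d$shape2,
                 printed = as.numeric(e$printed), value = value)
    }))
  }))
  bad <- !(rows$from %in% .activity_states) | !(rows$to %in% .activity_states)
  if (any(bad)) stop("activity_transitions reference unknown states: ",
                     paste(unique(c(rows$from[bad], rows$to[bad])), collapse = ", "))
  # canonical row order: arm, then from-major, to-minor
  ord <- order(match(rows$arm, .arms), match(rows$from, .activity_states),
               match(rows$to, .activity_states))
  rows <- rows[ord, ]
  rownames(rows) <- NULL
  rows
}

parse_incidence <- function(block) {
  m <- matrix(NA_real_, 3, 5, dimnames = list(.activity_states, .disease_states))
  for (a in .activity_states) {
    if (is.null(block[[a]])) stop("disease_incidence missing row '", a, "'")
    v <- unlist(block[[a]])
    if (!setequal(names(v), .disease_states))
      stop("disease_incidence.", a, " must cover the five disease states")
    m[a, ] <- v[.disease_states]
  }
  m
}

parse_payoff_block <- function(block, group_col, groups) {
  if (!setequal(names(block), groups))
    stop("payoff block must have sections: ", paste(groups, collapse = ", "))
  rows <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(block[[g]], function(e) {
      d <- parse_entry_dist(e, paste0(group_col, " ", g, ", state ", e$state))
      value <- if (!is.null(e$value)) as.numeric(e$value) else as.numeric(e$printed)
      r <- data.frame(g, state = e$state, family = d$family,
                      shape1 = d$shape1, shape2 = d$shape2,
                      printed = as.numeric(e$printed), value = value)
      names(r)[1] <- group_col
      r
    }))
  }))
  bad <- !(rows$state %in% .states)
  if (any(bad)) stop("payoff block references unknown states: ",
                     paste(unique(rows$state[bad]), collapse = ", "))
  ord <- order(match(rows[[group_col]], groups), match(rows$state, .states))
  rows <- rows[ord, ]
  rownames(rows) <- NULL
  rows
}

# ---- overrides ----------------------------------------------------------

apply_overrides <- function(params, overrides) {
  if (!length(overrides)) return(params)
  if (is.null(names(overrides)) || any(names(overrides) == ""))
    stop("overrides must be a named list")
  for (key in names(overrides)) {
    params <- apply_one_override(params, key, overrides[[key]])
  }
  params
}

scalar_override_keys <- c(
  "cohort_size", "horizon_years", "cycle_length_years",
  "discount_rate_costs", "discount_rate_effects", "effect_duration_years",
  "perspective", "utility_source", "program_cost"
)

apply_one_override <- function(params, key, value) {
  if (key %in% scalar_override_keys) {
    if (key == "effect_duration_years" && identical(value, "horizon")) value <- Inf
    if (key == "horizon_years") value <- as.integer(value)
    params[[key]] <- value
    return(params)
  }
  if (key == "initial_activity") {
    v <- unlist(value)
    if (!setequal(names(v), .activity_states))
      stop("override 'initial_activity' must name the three activity states")
    params$initial_activity <- v[.activity_states]
    return(params)
  }
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  set_cell <- function(tab, sel, field, what) {
    i <- which(sel)
    if (length(i) != 1) stop("override '", key, "': no such ", what)
    if (!field %in% c("value", "printed", "shape1", "shape2", "family"))
      stop("override '", key, "': unknown field '", field, "'")
    tab[i, field] <- value
    tab
  }
  switch(parts[1],
    activity_transitions = {
      if (length(parts) != 5) stop("override '", key,
        "' must be activity_transitions.<arm>.<from>.<to>.<field>")
      tr <- params$activity_transitions
      params$activity_transitions <- set_cell(tr,
        tr$arm == parts[2] & tr$from == parts[3] & tr$to == parts[4],
        parts[5], "transition entry")
    },
    utilities = {
      if (length(parts) != 4) stop("override '", key,
        "' must be utilities.<source>.<state>.<field>")
      ut <- params$utilities
      params$utilities <- set_cell(ut,
        ut$source == parts[2] & ut$state == parts[3], parts[4], "utility entry")
    },
    annual_costs = {
      if (length(parts) != 4) stop("override '", key,
        "' must be annual_costs.<perspective>.<state>.<field>")
      co <- params$annual_costs
      params$annual_costs <- set_cell(co,
        co$perspective == parts[2] & co$state == parts[3], parts[4],
        "cost entry")
    },
    disease_incidence = {
      if (length(parts) != 3 || !parts[2] %in% .activity_states ||
          !parts[3] %in% .disease_states)
        stop("override '", key, "' must be disease_incidence.<activity>.<disease>")
      params$disease_incidence[parts[2], parts[3]] <- value
    },
    activity_mortality = {
      if (length(parts) != 2 || !parts[2] %in% .activity_states)
        stop("override '", key, "' must be activity_mortality.<activity>")
      params$activity_mortality[parts[2]] <- value
    },
    disease_mortality = {
      if (length(parts) != 2 || !parts[2] %in% .disease_states)
        stop("override '", key, "' must be disease_mortality.<disease>")
      params$disease_mortality[parts[2]] <- value
    },
    stop("unknown override key: '", key, "'")
  )
  params
}

# ---- active payoff / transition accessors -------------------------------

# utility per person-year for all 9 states under the active utility source
active_utilities <- function(params) {
  ut <- params$utilities
  act_src <- if (params$utility_source == "trial") "trial" else "literature"
  act <- ut[ut$source == act_src, ]
  dis <- ut[ut$source == "condition", ]
  u <- c(act$value[match(.activity_states, act$state)],
         dis$value[match(.disease_states, dis$state)], 0)
  names(u) <- .states
  u
}

# annual cost per person-year for all 9 states under the active perspective
active_costs <- function(params) {
  co <- params$annual_costs[params$annual_costs$perspective == params$perspective, ]
  cc <- c(co$value[match(c(.activity_states, .disease_states), co$state)], 0)
  names(cc) <- .states
  cc
}

# 3x3 activity-to-activity working values for one arm (rows = from).
# The loader and every setter keep the transition table in canonical order
# (eurofit block then control block, from-major within each), so the nine
# arm values can be read positionally.
activity_matrix <- function(params, arm) {
  idx <- if (arm == "eurofit") 1:9 else 10:18
  matrix(params$activity_transitions$value[idx], 3, 3, byrow = TRUE,
         dimnames = list(.activity_states, .activity_states))
}
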