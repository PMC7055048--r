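#' Generate a synthetic activity-transition trial
#'
#' Emulates the randomised-trial data from which the model's
#' activity-transition probabilities are estimated: per arm, each
#' participant has a baseline activity category drawn from the initial
#' activity distribution and a 12-month category drawn from the row of
#' the arm's true transition matrix. Transitions are generated directly
#' at 12 months (the model's cycle); there is no monthly substructure.
#'
#' @param n_per_arm Participants per arm.
#' @param true_transitions Named list (`eurofit`, `control`) of 3 x 3
#'   row-stochastic matrices over the activity states.
#' @param initial_dist Baseline activity proportions (length 3, sums
#'   to 1).
#' @param seed Integer seed; the generator is reproducible.
#' @return A `synthetic_trial` object: a data.frame with columns `id`,
#'   `arm`, `baseline`, `month12`, with the generating matrices, sizes
#'   and seed as attributes.
#' @export
#' @examples
#' tr <- diag(3); dimnames(tr) <- rep(list(c("inactive", "moderate",
#'   "recommended")), 2)
#' generate_trial(10, list(eurofit = tr, control = tr),
#'                c(0.175, 0.105, 0.720), seed = 1)
generate_trial <- function(n_per_arm, true_transitions, initial_dist,
                           seed = 1) {
  stopifnot(n_per_arm >= 1)
  if (!setequal(names(true_transitions), .arms))
    stop("true_transitions must be a list with elements 'eurofit' and 'control'")
  for (arm in .arms) {
    m <- true_transitions[[arm]]
    if (!all(dim(m) == c(3, 3)) || any(m < 0) ||
        any(abs(rowSums(m) - 1) > 1e-9))
      stop("true_transitions$", arm, " must be a 3 x 3 row-stochastic matrix")
  }
  initial_dist <- initial_dist / sum(initial_dist)

  set.seed(seed)
  tabs <- lapply(.arms, function(arm) {
    baseline <- sample(.activity_states, n_per_arm, replace = TRUE,
                       prob = initial_dist)
    month12 <- character(n_per_arm)
    for (a in .activity_states) {
      idx <- which(baseline == a)
      if (length(idx))
        month12[idx] <- sample(.activity_states, length(idx), replace = TRUE,
                               prob = true_transitions[[arm]][a, ])
    }
    data.frame(arm = arm, baseline = baseline, month12 = month12)
  })
  out <- do.call(rbind, tabs)
  out <- cbind(id = seq_len(nrow(out)), out)
  structure(out, true_transitions = true_transitions,
            n_per_arm = n_per_arm, seed = seed,
            class = c("synthetic_trial", "data.frame"))
}

#' Estimate transition probabilities from trial data
#'
#' Row-wise observed fractions: the estimated probability of moving from
#' baseline category `a` to 12-month category `b` is the number of
#' participants who did so divided by the number starting in `a`. Each
#' cell also receives a conjugate-count beta specification
#' (alpha = transitions observed, beta = row total minus transitions),
#' the form the PSA samples from. Cells whose beta parameter is 0 (all
#' of a row's mass in one cell) are flagged degenerate.
#'
#' @param trial A `synthetic_trial` (or any data.frame with `arm`,
#'   `baseline`, `month12` columns over the activity states).
#' @param arm `"eurofit"` or `"control"`.
#' @return A list with `point` (3 x 3 matrix of observed fractions, rows
#'   summing to 1), `alpha` and `beta` (3 x 3 conjugate count matrices),
#'   `row_n` (baseline counts) and `degenerate` (logical 3 x 3).
#' @export
estimate_transitions <- function(trial, arm = .arms) {
  arm <- match.arg(arm)
  d <- trial[trial$arm == arm, ]
  counts <- table(factor(d$baseline, levels = .activity_states),
                  factor(d$month12, levels = .activity_states))
  counts <- matrix(as.numeric(counts), 3, 3,
                   dimnames = list(.activity_states, .activity_states))
  row_n <- rowSums(counts)
  empty <- row_n == 0
  if (any(empty))
    stop("no participants with baseline category: ",
         paste(.activity_states[empty], collapse = ", "))
  point <- counts / row_n
  beta <- row_n - counts
  list(point = point, alpha = counts, beta = beta, row_n = row_n,
       degenerate = beta == 0)
}

#' Build model parameters from synthetic-trial estimates
#'
#' Replaces the activity-transition block of a parameter set with the
#' estimates from a synthetic trial: the observed fractions become the
#' working values and the conjugate counts the PSA beta parameters
#' (degenerate cells, with zero observed failures or successes, are kept
#' fixed since a beta distribution requires positive parameters). All
#' other parameters are left unchanged, so the full deterministic and
#' probabilistic pipeline can run on trial-estimated inputs.
#'
#' @param trial A `synthetic_trial`.
#' @param base A `ce_params` object supplying every non-transition
#'   parameter, default [eurofit_params()].
#' @return A validated `ce_params` object.
#' @export
params_from_trial <- function(trial, base = eurofit_params()) {
  tr <- base$activity_transitions
  for (arm in .arms) {
    est <- estimate_transitions(trial, arm)
    for (from in .activity_states) for (to in .activity_states) {
      i <- which(tr$arm == arm & tr$from == from & tr$to == to)
      a <- est$alpha[from, to]; b <- est$beta[from, to]
      tr$value[i] <- est$point[from, to]
      tr$printed[i] <- est$point[from, to]
      if (a > 0 && b > 0) {
        tr$family[i] <- "beta"; tr$shape1[i] <- a; tr$shape2[i] <- b
      } else {
        tr$family[i] <- "fixed"; tr$shape1[i] <- NA_real_; tr$shape2[i] <- NA_real_
      }
    }
  }
  base$activity_transitions <- tr
  validate_parameters(base)
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial> %d participants per arm (seed %d)\n",
              attr(x, "n_per_arm"), attr(x, "seed")))
  print(table(x$arm, x$baseline))
  invisible(x)
}
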