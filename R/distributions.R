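#' Parameter distribution specification
#'
#' Every model input carries both a deterministic value and a sampling
#' distribution for probabilistic sensitivity analysis (PSA). Parameters
#' estimated from the randomised trial are `beta` (probabilities,
#' utilities) or `gamma` (costs); literature-sourced parameters are
#' `fixed` and are never perturbed in the PSA.
#'
#' @param family `"beta"`, `"gamma"` or `"fixed"`.
#' @param shape1 Beta alpha or gamma shape; `NA` for fixed parameters.
#' @param shape2 Beta beta or gamma scale; `NA` for fixed parameters.
#' @param value Deterministic value on the natural scale (probability,
#'   utility, or euros per year).
#' @return A list of class `dist_spec`.
#' @export
#' @examples
#' dist_spec("beta", 4.0, 17.0, value = 4.0 / 21.0)
#' dist_spec("gamma", 0.19, 12658, value = 2436)
#' dist_spec("fixed", value = 0.4)
dist_spec <- function(family = c("fixed", "beta", "gamma"),
                      shape1 = NA_real_, shape2 = NA_real_, value) {
  family <- match.arg(family)
  if (family != "fixed") {
    if (!is.finite(shape1) || shape1 <= 0)
      stop("dist_spec: shape1 must be > 0 for family '", family, "'")
    if (!is.finite(shape2) || shape2 <= 0)
      stop("dist_spec: shape2 must be > 0 for family '", family, "'")
  }
  if (!is.finite(value)) stop("dist_spec: value must be finite")
  if (family == "beta" && (value < 0 || value > 1))
    stop("dist_spec: beta value must lie in [0, 1]")
  if (family == "gamma" && value < 0)
    stop("dist_spec: gamma value must be >= 0")
  structure(list(family = family, shape1 = shape1, shape2 = shape2,
                 value = value), class = "dist_spec")
}

#' Mean of a parameter distribution
#'
#' Beta mean `shape1 / (shape1 + shape2)`, gamma mean `shape1 * shape2`,
#' or the stored value for fixed parameters.
#'
#' @param spec A [dist_spec()].
#' @return Numeric scalar.
#' @export
dist_mean <- function(spec) {
  switch(spec$family,
    beta  = spec$shape1 / (spec$shape1 + spec$shape2),
    gamma = spec$shape1 * spec$shape2,
    fixed = spec$value
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  lab <- switch(x$family,
    beta  = sprintf("Beta(alpha = %g, beta = %g)", x$shape1, x$shape2),
    gamma = sprintf("Gamma(shape = %g, scale = %g)", x$shape1, x$shape2),
    fixed = "Fixed"
  )
  cat(sprintf("<dist_spec> value = %g, %s\n", x$value, lab))
  invisible(x)
}

# Vectorised draw over the rows of a parameter table (columns family,
# shape1, shape2, value). Fixed rows keep their value. Draw order is the
# row order of the table, which the loader keeps canonical, so results
# are reproducible for a given RNG state.
sample_param_table <- function(tab) {
  b <- tab$family == "beta"
  if (any(b)) tab$value[b] <- stats::rbeta(sum(b), tab$shape1[b], tab$shape2[b])
  g <- tab$family == "gamma"
  if (any(g)) tab$value[g] <- stats::rgamma(sum(g), shape = tab$shape1[g],
                                            scale = tab$shape2[g])
  tab
}
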