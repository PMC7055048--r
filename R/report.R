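#' Export model outputs as CSV
#'
#' Writers for the package's tabular outputs: a cohort trace (cycle by
#' state occupancy), a set of cost-effectiveness results in the layout
#' of the published results table, and an acceptability curve.
#'
#' @param x The object to write (a `ce_trace`, a named list of
#'   `ce_result`s, or a `ce_ceac`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @name export_csv
NULL

#' @rdname export_csv
#' @export
write_trace_csv <- function(x, path) {
  stopifnot(inherits(x, "ce_trace"))
  df <- data.frame(cycle = as.integer(rownames(x)),
                   arm = attr(x, "arm"), unclass(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_csv
#' @export
write_results_csv <- function(x, path) {
  if (inherits(x, "ce_result")) x <- list(result = x)
  rows <- do.call(rbind, Map(ce_row, x, names(x)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_csv
#' @export
write_ceac_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: the md5 of the parameter
#' configuration, the seed, the scenario names, the package version,
#' a timestamp, and the md5 of every output file. Rerunning the same
#' analysis with the same seed reproduces all listed outputs
#' bit-exactly.
#'
#' @param path Manifest output file (YAML).
#' @param config_path Parameter configuration the run used.
#' @param seed Root seed of the run (`NA` for purely deterministic runs).
#' @param scenarios Character vector of scenario names run.
#' @param outputs Character vector of output file paths; all must exist.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config_path, seed = NA_integer_,
                               scenarios = character(), outputs = character()) {
  missing <- outputs[!file.exists(outputs)]
  if (length(missing))
    stop("manifest lists missing output file(s): ",
         paste(missing, collapse = ", "))
  manifest <- list(
    package = "eurofitce",
    version = as.character(utils::packageVersion("eurofitce")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = list(path = config_path,
                  md5 = unname(tools::md5sum(config_path))),
    scenarios = as.list(scenarios),
    outputs = lapply(outputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
  )
  writeLines(yaml::as.yaml(manifest), path)
  invisible(path)
}

#' Plot the cost-effectiveness plane
#'
#' Scatter of the incremental cost-effect pairs of a PSA, with the
#' willingness-to-pay threshold drawn through the origin.
#'
#' @param psa A `ce_psa`.
#' @param wtp Willingness-to-pay threshold (euro per QALY) for the
#'   reference line.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = 22000) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_ce_plane requires the ggplot2 package")
  d <- psa$draws
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_qalys, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4, colour = "steelblue") +
    ggplot2::geom_abline(intercept = 0, slope = wtp, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (euro)",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("%s simulations; dashed line: %s euro/QALY",
                                     format(psa$n_sims, big.mark = ","),
                                     format(wtp, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param ceacs A named list of `ce_ceac` objects (or a single one).
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceacs) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_ceac requires the ggplot2 package")
  if (inherits(ceacs, "ce_ceac")) ceacs <- list(base = ceacs)
  d <- do.call(rbind, Map(function(x, nm)
    cbind(as.data.frame(x), analysis = nm), ceacs, names(ceacs)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$probability,
                                  colour = .data$analysis)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (euro per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::theme_minimal()
}
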