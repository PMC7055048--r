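#!/usr/bin/env Rscript
# Deterministic scenario and sensitivity analyses: the four published
# scenarios (10-year horizon, healthcare perspective, literature
# utilities, one-year intervention effect) plus the discount-rate grid
# (0% and 5% on costs, effects, and both), summarised as a results table
# and a tornado table of ICER changes versus the base case.
#
# Usage: Rscript analysis/02_scenarios.R
# Writes: results/scenarios.csv, results/tornado.csv, results/manifest_02.yaml

suppressPackageStartupMessages(library(eurofitce))
dir.create("results", showWarnings = FALSE)

params <- eurofit_params()
specs <- c(canonical_scenarios(), discount_scenarios())

results <- lapply(specs, function(s) run_scenario(params, s))
write_results_csv(results, "results/scenarios.csv")

for (nm in names(canonical_scenarios())) {
  r <- results[[nm]]
  lab <- if (r$verdict == "dominant")
    sprintf("dominant (saves %.0f euro, gains %.0f QALYs)",
            -r$incremental_cost, r$incremental_qalys)
  else sprintf("ICER %.0f euro/QALY", r$icer)
  cat(sprintf("%-22s %s\n", nm, lab))
}

tor <- tornado(params, specs[-1])
write.csv(tor, "results/tornado.csv", row.names = FALSE)
cat("\nICER change vs base case (tornado):\n")
print(tor[order(-abs(tor$pct_change_vs_base)), ], row.names = FALSE,
      digits = 3)

write_run_manifest(
  "results/manifest_02.yaml",
  config_path = system.file("extdata", "eurofit_params.yaml",
                            package = "eurofitce"),
  scenarios = names(specs),
  outputs = c("results/scenarios.csv", "results/tornado.csv")
)
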