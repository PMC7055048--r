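#!/usr/bin/env Rscript
# Probabilistic sensitivity analysis for the base case: 25,000 Monte
# Carlo simulations sampling every trial-derived parameter (beta for
# transitions and utilities, gamma for costs), credibility intervals for
# the incremental cost and QALYs, the cost-effectiveness plane and the
# acceptability curve.
#
# Usage: Rscript analysis/03_psa.R [seed] [n_sims]
# Writes: results/psa_draws.csv, results/ceac_base.csv,
#         results/psa_summary.csv, results/manifest_03.yaml
#         (+ results/fig_ce_plane.pdf, results/fig_ceac_base.pdf
#            when ggplot2 is available)

suppressPackageStartupMessages(library(eurofitce))
dir.create("results", showWarnings = FALSE)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 2026L
n_sims <- if (length(args) >= 2) as.integer(args[2]) else 25000L

params <- eurofit_params()
cat(sprintf("running %s simulations (seed %d)...\n",
            format(n_sims, big.mark = ","), seed))
psa <- run_psa(params, n_sims = n_sims, seed = seed)
print(psa)

ceac <- compute_ceac(psa)
for (wtp in c(10000, 22000, 34000))
  cat(sprintf("P(cost-effective at %s euro/QALY) = %.2f\n",
              format(wtp, big.mark = ","),
              ceac$probability[ceac$threshold == wtp]))

write.csv(psa$draws, "results/psa_draws.csv", row.names = FALSE)
write_ceac_csv(ceac, "results/ceac_base.csv")
write.csv(summary(psa), "results/psa_summary.csv", row.names = FALSE)
outputs <- c("results/psa_draws.csv", "results/ceac_base.csv",
             "results/psa_summary.csv")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  ggplot2::ggsave("results/fig_ce_plane.pdf", plot_ce_plane(psa),
                  width = 6, height = 5)
  ggplot2::ggsave("results/fig_ceac_base.pdf", plot_ceac(ceac),
                  width = 6, height = 4)
  outputs <- c(outputs, "results/fig_ce_plane.pdf", "results/fig_ceac_base.pdf")
}

write_run_manifest(
  "results/manifest_03.yaml",
  config_path = system.file("extdata", "eurofit_params.yaml",
                            package = "eurofitce"),
  seed = seed, scenarios = "base", outputs = outputs
)
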