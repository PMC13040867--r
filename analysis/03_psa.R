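#!/usr/bin/env Rscript
# Probabilistic sensitivity analysis: joint Monte Carlo sampling of every
# model input from its assigned distribution, 10,000 re-evaluations of both
# arms per model, incremental scatter, percentile summaries and
# cost-effectiveness acceptability curves over 0-150,000 USD/QALY.
#
# Usage: Rscript analysis/03_psa.R [n_draws] [seed]
# Writes: results/psa_model{1,2}_samples.csv, results/psa_model{1,2}_ceac.csv,
#         results/psa_model{1,2}_summary.json, scatter/CEAC plots when
#         ggplot2 is available, results/psa_manifest.json

suppressPackageStartupMessages(library(periomel))
argv <- commandArgs(trailingOnly = TRUE)
n_draws <- if (length(argv) >= 1) as.integer(argv[1]) else 10000L
seed <- if (length(argv) >= 2) as.integer(argv[2]) else 20260920L
dir.create("results", showWarnings = FALSE)
outputs <- character()

for (mid in 1:2) {
  ps <- suppressWarnings(load_parameters(model_id = mid))
  cat(sprintf("\n== Model %d PSA: %d draws, seed %d ==\n", mid, n_draws, seed + mid - 1L))
  psa <- suppressWarnings(run_psa(ps, n_draws = n_draws, seed = seed + mid - 1L))
  print(psa)
  if (psa$n_resampled > 0) {
    cat(sprintf("%d draw(s) failed evaluation and were redrawn.\n", psa$n_resampled))
  }

  samples_csv <- sprintf("results/psa_model%d_samples.csv", mid)
  write.csv(psa$samples, samples_csv, row.names = FALSE)
  ceac_csv <- sprintf("results/psa_model%d_ceac.csv", mid)
  write.csv(psa$ceac, ceac_csv, row.names = FALSE)
  summary_json <- sprintf("results/psa_model%d_summary.json", mid)
  jsonlite::write_json(psa$summary, summary_json, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, samples_csv, ceac_csv, summary_json)

  if (requireNamespace("ggplot2", quietly = TRUE)) {
    library(ggplot2)
    sc <- scatter_export(psa)
    p1 <- ggplot(sc, aes(delta_qaly, delta_cost)) +
      geom_point(alpha = 0.15, size = 0.6, colour = "steelblue") +
      geom_abline(slope = attr(sc, "wtp"), intercept = 0, linetype = 2) +
      geom_hline(yintercept = 0, colour = "grey40") +
      geom_vline(xintercept = 0, colour = "grey40") +
      labs(x = "Incremental QALY", y = "Incremental cost (USD)",
           title = sprintf("Model %d: incremental cost vs QALY (%d draws)",
                           mid, n_draws),
           subtitle = "Dashed line: willingness-to-pay 100,000 USD/QALY") +
      theme_minimal()
    scatter_png <- sprintf("results/psa_model%d_scatter.png", mid)
    ggsave(scatter_png, p1, width = 7, height = 5, dpi = 150)
    p2 <- ggplot(psa$ceac, aes(wtp, prob_cost_effective)) +
      geom_line(colour = "steelblue") +
      coord_cartesian(ylim = c(0, 1)) +
      labs(x = "Willingness-to-pay (USD/QALY)",
           y = "Probability cost-effective",
           title = sprintf("Model %d: cost-effectiveness acceptability curve", mid)) +
      theme_minimal()
    ceac_png <- sprintf("results/psa_model%d_ceac.png", mid)
    ggsave(ceac_png, p2, width = 7, height = 4, dpi = 150)
    outputs <- c(outputs, scatter_png, ceac_png)
  }
}

jsonlite::write_json(
  list(command = "analysis/03_psa.R", n_draws = n_draws, seed = seed,
       package_version = as.character(packageVersion("periomel")),
       timestamp = format(Sys.time(), tz = "UTC"), outputs = outputs),
  "results/psa_manifest.json", auto_unbox = TRUE, null = "null")
cat("\nOutputs written under results/.\n")
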