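#!/usr/bin/env Rscript
# How reliably is the injected negative signal-curvature dependence
# recovered as noise grows?  For both curved phantoms, sweep the noise level
# from noiseless to twice the level calibrated for r = -0.85 and record the
# Spearman correlation recovery rate over 200 seeded replicates each.

suppressPackageStartupMessages(library(vesselwss))

out_dir <- "results/signal_analysis"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

arc_centerline <- function(R, L = 50, ds = 1) {
  s <- seq(0, L, by = ds)
  th <- s / R
  centerline(cbind(R * (1 - cos(th)), 0, R * sin(th)),
             tangents = cbind(sin(th), 0, cos(th)))
}

rows <- list()
for (phantom in c("curve_high", "curve_low")) {
  R <- if (phantom == "curve_high") 15 else 40
  cl <- arc_centerline(R)
  sigma_85 <- calibrate_signal_noise(cl, slope = -1, target_r = 0.85)
  for (mult in c(0, 0.5, 1, 1.5, 2)) {
    sims <- vapply(1:200, function(seed) {
      prof <- generate_signal_profile(cl, slope = -1,
                                      noise_sd = mult * sigma_85,
                                      seed = seed)
      sc <- signal_gamma_correlation(prof)
      c(r = sc$r, hit = as.numeric(sc$r < 0 && sc$p < 0.05))
    }, numeric(2))
    rows[[length(rows) + 1L]] <- data.frame(
      phantom = phantom, noise_multiple = mult,
      noise_sd = mult * sigma_85,
      mean_r = mean(sims["r", ]), sd_r = stats::sd(sims["r", ]),
      recovery_rate = mean(sims["hit", ])
    )
  }
}
sweep_tab <- do.call(rbind, rows)
write.csv(sweep_tab, file.path(out_dir, "noise_sweep.csv"),
          row.names = FALSE)
cat("Signal recovery under noise (results/signal_analysis/noise_sweep.csv):\n")
print(sweep_tab, row.names = FALSE, digits = 3)
cat(sprintf(
  "\nAt the calibrated noise level the mean recovered r is %.2f (curve-H) / %.2f (curve-L)\nand the negative dependence is detected (p < 0.05) in %.0f%% / %.0f%% of replicates.\n",
  sweep_tab$mean_r[sweep_tab$phantom == "curve_high" &
                     sweep_tab$noise_multiple == 1],
  sweep_tab$mean_r[sweep_tab$phantom == "curve_low" &
                     sweep_tab$noise_multiple == 1],
  100 * sweep_tab$recovery_rate[sweep_tab$phantom == "curve_high" &
                                  sweep_tab$noise_multiple == 1],
  100 * sweep_tab$recovery_rate[sweep_tab$phantom == "curve_low" &
                                  sweep_tab$noise_multiple == 1]
))
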