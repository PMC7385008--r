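#!/usr/bin/env Rscript
# The phantom study end to end: paired "segmentations" of each phantom with
# segmentation-like perturbations (one unbiased, one 5% under-estimating,
# both with smooth 0.05 mm radial noise), centerline extraction, 1 mm area
# profiling, and pairwise agreement statistics.  Produces the study's
# headline table (error metric E_A, Darcy-Weisbach-chained E_WSS, mean
# diameter difference +/- SD per phantom), Bland-Altman tables, and the
# signal-intensity vs flow-direction-derivative correlations.

suppressPackageStartupMessages(library(vesselwss))

cfg <- phantom_study_config(out_dir = "results/phantom_study", seed = 1L)
res <- run_phantom_study(cfg)

cat("\nPhantom study report (results/phantom_study/table1.csv):\n")
print(res$table1, row.names = FALSE, digits = 3)
cat("\nSignal correlations (results/phantom_study/signal_correlations.csv):\n")
print(res$signal, row.names = FALSE, digits = 3)

cat("\nObservations:\n")
cat(sprintf(
  " - mean diameter differences span %.2f to %.2f mm (configured bias: -5%% on source B)\n",
  min(res$table1$mean_diff_mm), max(res$table1$mean_diff_mm)
))
cat(sprintf(
  " - E_WSS exceeds E_A for every phantom (wall shear amplifies area error): %s\n",
  paste(sprintf("%.2f>%.2f", res$table1$E_WSS, res$table1$E_A),
        collapse = ", ")
))
curved <- res$signal[res$signal$phantom %in% c("curve_high", "curve_low"), ]
cat(sprintf(
  " - curved phantoms: Spearman r(intensity, Gamma') = %s (injected negative dependence)\n",
  paste(sprintf("%.2f", curved$spearman_r), collapse = ", ")
))
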