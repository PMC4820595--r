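#!/usr/bin/env Rscript
# Image-quality track: simulate the NEMA NU 4 IQ phantom acquisition at every
# study window, reconstruct the nested correction sets (AC / AC+SC /
# AC+SC+PGF) with 2D FBP, and compute nonuniformity, recovery coefficients,
# spillover ratios and the weighted SOR. Writes the full report bundle under
# results/iq_study/.

suppressPackageStartupMessages(library(pgfpet))

config <- study_config(necr_activities = NULL, seed = 20160322)
cat("Running the image-quality study:",
    length(config$windows), "windows x",
    length(config$correction_sets), "correction sets",
    sprintf("(count scale %.3g)\n", config$count_scale))
bundle <- run_study(config)

files <- write_report(bundle, "results/iq_study")
cat("wrote:", paste(basename(files), collapse = ", "), "\n\n")

final <- bundle$iq[bundle$iq$correction_set == "AC+SC+PGF",
                   c("window", "nonuniformity_pct", "sor_air_pct",
                     "sor_water_pct", "wsor")]
cat("Fully corrected images (AC+SC+PGF):\n")
print(final, digits = 3, row.names = FALSE)
cat(sprintf("\nSimulated-study optimal window (min wSOR): %s\n",
            window_label(bundle$optimal_window)))

# effect of the prompt-gamma correction on spillover, averaged over windows
by_set <- aggregate(cbind(sor_air_pct, sor_water_pct) ~ correction_set,
                    bundle$iq, mean)
cat("\nMean SOR by correction set (percentage points):\n")
print(by_set, digits = 3, row.names = FALSE)
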