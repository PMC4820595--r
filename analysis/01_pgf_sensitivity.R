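#!/usr/bin/env Rscript
# Prompt gamma coincidence fractions from paired-isotope sensitivities.
#
# Two routes to the same table:
#   (a) the published branching-ratio-uncorrected sensitivities of 124I and
#       18F, pushed through the branching-ratio correction and the PGF
#       formula;
#   (b) a full simulation of the sensitivity protocol (506 kBq 124I / 673 kBq
#       18F line sources, 5 min scans, 1 h background scan) for all eleven
#       study windows, with the published PGFs injected as ground truth.

suppressPackageStartupMessages(library(pgfpet))
dir.create("results", showWarnings = FALSE)
set.seed(20160322)

i124 <- isotope("I124"); f18 <- isotope("F18")

# (a) from the published sensitivities
sens <- published_sensitivities()
sens$s_i124_corr <- branching_ratio_correct(sens$s_i124_pct, i124)
sens$s_f18_corr <- branching_ratio_correct(sens$s_f18_pct, f18)
sens$pgf <- mapply(compute_pgf, sens$s_i124_corr, sens$s_f18_corr)
cat("PGF from published sensitivities:\n")
print(cbind(window = sprintf("%d~%d", sens$lld_keV, sens$uld_keV),
            round(sens[, c("s_i124_corr", "s_f18_corr", "pgf")], 3)))
write.csv(sens, "results/pgf_from_published_sensitivities.csv",
          row.names = FALSE)

# (b) simulated sensitivity acquisitions across all study windows
est <- suppressWarnings(
  estimate_pgf_table(study_windows(), config = acquisition_config(),
                     duration_s = 300, seed = 20160322)
)
truth <- published_pgf_table()
est$pgf_true <- mapply(function(l, u) pgf_for_window(truth, energy_window(l, u)),
                       est$lld_keV, est$uld_keV)
cat("\nSimulated-protocol PGF estimates vs injected truth:\n")
print(round(as.data.frame(est), 3))
cat(sprintf("max |error| = %.4f\n", max(abs(est$pgf - est$pgf_true))))
write.csv(as.data.frame(est), "results/pgf_estimated_from_simulation.csv",
          row.names = FALSE)
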