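#!/usr/bin/env Rscript
# Target attainment as a function of the MIC evaluated: fT>MIC over a
# doubling-dilution grid around the 4 ug/mL cut-off, per compartment.
# Writes results/mic_sweep.csv.

library(deadspacePK)

st <- load_study("results/study/doses.csv", "results/study/dialysates.csv",
                 "results/study/plasma.csv", "results/study/catheters.csv")
rec <- readr::read_csv("results/recoveries.csv", show_col_types = FALSE)
prof <- build_cohort_profiles(st, rec)

mics <- c(0.5, 1, 2, 4, 8, 16)
sw <- mic_sweep(prof, mics)
readr::write_csv(sw, "results/mic_sweep.csv")

agg <- stats::aggregate(t_above_mic ~ compartment + mic, sw, mean)
message("Mean total-per-interval fT>MIC (min) by MIC:")
for (cm in unique(agg$compartment)) {
  s <- agg[agg$compartment == cm, ]
  s <- s[order(s$mic), ]
  message(sprintf("  %-10s %s", cm,
                  paste(sprintf("%g:%0.f", s$mic, s$t_above_mic),
                        collapse = "  ")))
}
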