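#!/usr/bin/env Rscript
# Relative-recovery calibration by internal-calibrator (meropenem) loss:
# one time-constant recovery per catheter, averaged over all usable
# collection intervals, with cohort-mean imputation for catheters whose
# calibrator channel is unusable. Reads the study written by 01, writes
# results/recoveries.csv.

library(deadspacePK)

st <- load_study("results/study/doses.csv", "results/study/dialysates.csv",
                 "results/study/plasma.csv", "results/study/catheters.csv",
                 subjects_csv = "results/study/subjects.csv")
rec <- calibrate_cohort(st)
readr::write_csv(rec, "results/recoveries.csv")

by_comp <- split(rec$recovery_pct, rec$compartment)
for (cm in names(by_comp)) {
  message(sprintf("%-10s mean recovery %.0f%% (SD %.0f), n = %d",
                  cm, mean(by_comp[[cm]]), stats::sd(by_comp[[cm]]),
                  length(by_comp[[cm]])))
}
message(sum(rec$provenance == "imputed"), " catheter(s) imputed")
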