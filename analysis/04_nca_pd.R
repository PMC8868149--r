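#!/usr/bin/env Rscript
# Per subject x compartment x dosing interval metrics: linear-up/log-down
# AUC over [0, 450] and [480, 930] min, Cmax/Tmax, terminal half-life,
# tissue penetration (AUC ratio vs plasma), fT>MIC and time to reach the
# 4 ug/mL threshold. Writes results/nca_results.csv and results/pd_results.csv.

library(deadspacePK)

st <- load_study("results/study/doses.csv", "results/study/dialysates.csv",
                 "results/study/plasma.csv", "results/study/catheters.csv",
                 subjects_csv = "results/study/subjects.csv")
rec <- readr::read_csv("results/recoveries.csv", show_col_types = FALSE)
prof <- build_cohort_profiles(st, rec)

nca <- run_nca(prof)
pd <- run_pd(prof, mic = st$mic)
readr::write_csv(nca, "results/nca_results.csv")
readr::write_csv(pd, "results/pd_results.csv")

mean_by <- function(df, v) stats::aggregate(df[[v]],
  list(compartment = df$compartment, interval = df$interval_index), mean)
a <- mean_by(nca, "auc")
message("Mean AUC (min*ug/mL) by compartment and interval:")
for (i in seq_len(nrow(a))) {
  message(sprintf("  %-10s interval %d: %6.0f", a$compartment[i],
                  a$interval[i], a$x[i]))
}
f <- mean_by(pd, "t_above_mic")
message("Mean fT>MIC (min):")
for (i in seq_len(nrow(f))) {
  message(sprintf("  %-10s interval %d: %5.0f", f$compartment[i],
                  f$interval[i], f$x[i]))
}
message(sum(is.na(nca$lambda_eq)), " undefined terminal fits; ",
        sum(is.na(pd$tt_threshold)), " thresholds never reached")
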