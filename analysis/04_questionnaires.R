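#!/usr/bin/env Rscript
# Score the cohort's questionnaires (MFI-20 dimensions, BDI-II, ESS,
# SSS, SF-A/R sleep quality and time in bed) and apply the computable
# inclusion rules: at most 2 missing items per instrument and general
# fatigue above the sex/age 75th-percentile norm threshold. The shipped
# norm table is a synthetic placeholder, so the cut-off exercises the
# cascade rather than reproducing population norms.
#
# Reads:  results/data/cohort.csv
# Writes: results/scored_subjects.csv

library(arousalstrat)

cohort <- read_cohort("results/data/cohort.csv")
norms <- read_mfi_norms()
scored <- score_cohort(cohort, norms)
scored$group <- cohort$group
scored$stability_score <- cohort$stability_score
write.csv(scored, "results/scored_subjects.csv", row.names = FALSE)

cat(sprintf("scored %d subjects; %d included, %d excluded\n",
            nrow(scored), sum(scored$included), sum(!scored$included)))
print(table(exclusion = scored$exclusion_reason, useNA = "no"))
inc <- scored[scored$included, ]
cat("\nscale summaries (included subjects):\n")
for (v in c("general_fatigue", "mental_fatigue", "bdi_total",
            "ess_total", "sss", "sfar_quality", "sfar_time_in_bed")) {
  cat(sprintf("  %-18s %5.1f +/- %.1f\n", v, mean(inc[[v]], na.rm = TRUE),
              sd(inc[[v]], na.rm = TRUE)))
}
cat(sprintf("ESS > 10 (excessive daytime sleepiness): %d subjects\n",
            sum(inc$ess_flag_sleepy, na.rm = TRUE)))
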