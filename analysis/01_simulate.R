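#!/usr/bin/env Rscript
# Simulate the study's raw materials: a batch of 15-min resting EEG
# recordings with scripted vigilance trajectories (written as EDF, with
# the ground-truth stage script beside each), and a 102-subject cohort
# questionnaire table with the two arousal groups' scale distributions.
#
# Writes: results/data/*.edf, results/data/*_script.csv,
#         results/data/cohort.csv

library(arousalstrat)

seed <- 20260925L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# ten recordings, mixed trajectory profiles; 300 s at 256 Hz keeps the
# batch light while exercising every stage (full 900-s recordings are
# classified identically, only slower)
profiles <- rep(c("stable_high", "declining", "fluctuating"),
                length.out = 10)
truth <- data.frame(subject_id = character(0), profile = character(0),
                    true_score = integer(0))
for (i in seq_along(profiles)) {
  sid <- sprintf("S%03d", i)
  script <- make_stage_script(profiles[i], duration_s = 900,
                              seed = seed + i)
  rec <- synthesize_recording(script, sfreq = 256, seed = seed + 100 + i,
                              subject_id = sid)
  write_edf(rec, file.path(out, paste0(sid, ".edf")))
  write_stage_sequence(stage_sequence(sid, script$stages),
                       file.path(out, paste0(sid, "_script.csv")))
  truth <- rbind(truth, data.frame(subject_id = sid,
                                   profile = profiles[i],
                                   true_score = script$true_score))
  cat(sprintf("%s: %-12s true stability score %d\n", sid, profiles[i],
              script$true_score))
}
write.csv(truth, file.path(out, "eeg_truth.csv"), row.names = FALSE)

cohort <- generate_cohort(cohort_config(seed = seed))
write_cohort(cohort, file.path(out, "cohort.csv"))
cat(sprintf("cohort: %d subjects (%d non-hypoaroused / %d hypoaroused)\n",
            nrow(cohort), sum(cohort$group == "non_hypoaroused"),
            sum(cohort$group == "hypoaroused")))
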