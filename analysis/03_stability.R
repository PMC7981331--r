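#!/usr/bin/env Rscript
# Summarise each staged recording into the arousal stability score
# (1-11) and stratify into hypoaroused (<= 6) vs non-hypoaroused (>= 7)
# fatigue, then compare against the generator's ground truth.
#
# Reads:  results/stages/*_stages.csv, results/data/eeg_truth.csv
# Writes: results/stability.csv

library(arousalstrat)

stage_dir <- "results/stages"
truth <- read.csv("results/data/eeg_truth.csv")

rows <- lapply(list.files(stage_dir, pattern = "_stages\\.csv$",
                          full.names = TRUE), function(f) {
  sid <- sub("_stages\\.csv$", "", basename(f))
  sq <- read_stage_sequence(f, subject_id = sid)
  res <- stability_score(sq)
  data.frame(subject_id = sid, score = res$score, group = res$group,
             matched_criterion = res$matched_criterion,
             c_first_block = ifelse(is.na(res$c_first_block), NA,
                                    res$c_first_block))
})
stab <- do.call(rbind, rows)
stab <- merge(stab, truth, by = "subject_id")
write.csv(stab, "results/stability.csv", row.names = FALSE)

print(stab[, c("subject_id", "profile", "true_score", "score", "group")])
cat(sprintf("\nexact score recovery: %d/%d; within +/-1: %d/%d\n",
            sum(stab$score == stab$true_score), nrow(stab),
            sum(abs(stab$score - stab$true_score) <= 1), nrow(stab)))
cat(sprintf("hypoaroused fraction in this batch: %.1f%%\n",
            100 * mean(stab$group == "hypoaroused")))
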