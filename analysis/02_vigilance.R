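#!/usr/bin/env Rscript
# Stage the simulated EEG batch: band-limit and re-reference each
# recording, mask artifact segments, classify every 1-s segment into
# the seven vigilance stages, and export per-subject stage CSVs plus
# hypnogram-style time-course figures.
#
# Reads:  results/data/*.edf (from 01_simulate.R)
# Writes: results/stages/*_stages.csv, results/figures/*_timecourse.png

library(arousalstrat)

in_dir <- "results/data"
stage_dir <- "results/stages"
fig_dir <- "results/figures"
dir.create(stage_dir, recursive = TRUE, showWarnings = FALSE)
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

truth <- read.csv(file.path(in_dir, "eeg_truth.csv"))
files <- list.files(in_dir, pattern = "\\.edf$", full.names = TRUE)
for (f in files) {
  rec <- read_edf(f)
  pp <- preprocess_recording(rec)
  if (!pp$usable) {
    cat(rec$subject_id, "excluded: artifact fraction",
        round(mean(pp$mask), 3), "\n")
    next
  }
  sq <- classify_recording(pp$rec, pp$mask)
  write_stage_sequence(sq, file.path(stage_dir,
                                     paste0(rec$subject_id,
                                            "_stages.csv")))
  ggplot2::ggsave(
    file.path(fig_dir, paste0(rec$subject_id, "_timecourse.png")),
    plot_stage_timecourse(sq), width = 8, height = 2.5, dpi = 120)
  script <- read_stage_sequence(
    file.path(in_dir, paste0(rec$subject_id, "_script.csv")))
  keep <- !sq$artifact_mask
  agree <- mean(sq$stages[keep] == script$stages[keep])
  cat(sprintf("%s: %d/%d artifact segments, %.1f%% agreement with script\n",
              rec$subject_id, sum(pp$mask), length(pp$mask), 100 * agree))
}
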