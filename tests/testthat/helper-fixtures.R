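# Small signal fixtures built in code.

# a minimal multichannel recording with all three alpha ROIs plus the
# fronto-central set and a horizontal EOG pair
fixture_channels <- c("O1", "O2", "P3", "P4", "Pz", "F3", "F4", "Fz",
                      "FC1", "FC2", "Cz", "C3", "C4")

# coherent 10 Hz alpha recording, occipital-dominant
alpha_recording <- function(duration_s = 4, sfreq = 256, amp = 20,
                            subject_id = "fix") {
  n <- duration_s * sfreq
  tt <- (seq_len(n) - 1) / sfreq
  gain <- ifelse(fixture_channels %in% c("O1", "O2"), 2, 1)
  data <- outer(gain, amp * sin(2 * pi * 10 * tt))
  eog <- matrix(0, 2, n)
  recording(subject_id, sfreq,
            rbind(data, eog),
            c(fixture_channels, "HEOGL", "HEOGR"))
}

expect_stage <- function(features, expected,
                         cfg = classifier_config()) {
  defaults <- list(relative_alpha = 0, slowwave_relative = 0,
                   roi_alpha = c(occipital = 0, parietal = 0,
                                 frontal = 0),
                   sem_present = FALSE, spindle_present = FALSE,
                   kcomplex_present = FALSE)
  f <- utils::modifyList(defaults, features)
  expect_identical(classify_segment(f, cfg), expected)
}
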