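test_that("band powers: sinusoid concentration, zero signal, validation", {
  sfreq <- 256
  tt <- (seq_len(sfreq) - 1) / sfreq
  seg <- matrix(8 * sin(2 * pi * 10 * tt), nrow = 1)
  bp <- band_powers(seg, sfreq)
  expect_gt(bp[, "alpha"] / sum(bp), 0.95)
  # absolute scale: amplitude A contributes ~ A^2/2
  expect_equal(unname(bp[, "alpha"]), 32, tolerance = 0.05)
  expect_true(all(band_powers(matrix(0, 1, sfreq), sfreq) == 0))
  expect_error(band_powers(matrix(0, 1, 100), sfreq), "1 s")
  expect_error(band_powers(matrix(0, 1, 32), 32), ">= 64")
})

test_that("white-noise band powers scale with bandwidth on average", {
  set.seed(8)
  sfreq <- 256
  acc <- c(delta = 0, theta = 0, alpha = 0, beta = 0)
  for (i in 1:300) {
    bp <- band_powers(matrix(rnorm(sfreq), 1), sfreq)
    acc <- acc + bp[1, ]
  }
  # bin counts at 1 Hz resolution: delta [2,4) = 2, theta [4,7) = 3,
  # alpha [8,12) = 4, beta [12,25) = 13
  ratio <- acc / c(2, 3, 4, 13)
  expect_lt(max(ratio) / min(ratio), 1.15)
})

test_that("SEM detector: slow drifts yes, saccades and flat traces no", {
  sfreq <- 256
  tt <- (seq_len(3 * sfreq) - 1) / sfreq
  cfg <- classifier_config()
  expect_false(detect_sem(rep(0, 3 * sfreq), sfreq, cfg))
  expect_true(detect_sem(50 * sin(2 * pi * 0.3 * tt), sfreq, cfg))
  # fast large deflection is removed by the 0.1-1 Hz band-pass
  expect_false(detect_sem(200 * sin(2 * pi * 5 * tt), sfreq, cfg))
  # sub-amplitude drift is ignored
  expect_false(detect_sem(10 * sin(2 * pi * 0.3 * tt), sfreq, cfg))
  expect_error(detect_sem(NULL, sfreq, cfg), "no horizontal EOG")
})

test_that("graphoelement detector: injected spindle and K-complex", {
  set.seed(12)
  sfreq <- 256; n <- 30 * sfreq
  background <- matrix(rnorm(2 * n, sd = 5), 2, n)
  cfg <- classifier_config()
  base <- detect_graphoelements(background, cfg, sfreq = sfreq)
  expect_false(base$spindle)
  # 13 Hz, 0.8 s burst at ~4x the background envelope
  tt <- (seq_len(round(0.8 * sfreq)) - 1) / sfreq
  withsp <- background
  withsp[1, 1000 + seq_along(tt)] <- withsp[1, 1000 + seq_along(tt)] +
    40 * sin(2 * pi * 13 * tt)
  expect_true(detect_graphoelements(withsp, cfg, sfreq = sfreq)$spindle)
  # biphasic 150 uV peak-to-peak, 1 s wave
  kt <- (seq_len(sfreq) - 1) / sfreq
  withk <- background
  withk[2, 3000 + seq_len(sfreq)] <- withk[2, 3000 + seq_len(sfreq)] +
    75 * sin(2 * pi * kt)
  expect_true(detect_graphoelements(withk, cfg, sfreq = sfreq)$kcomplex)
  # a plain alpha segment has neither
  alpha <- matrix(20 * sin(2 * pi * 10 * (seq_len(n) - 1) / sfreq), 1)
  res <- detect_graphoelements(alpha, cfg, sfreq = sfreq)
  expect_false(res$spindle)
  expect_false(res$kcomplex)
})

test_that("segment classification follows the staged decision order", {
  expect_stage(list(relative_alpha = 0.7,
                    roi_alpha = c(occipital = 10, parietal = 5,
                                  frontal = 3)), "A1")
  expect_stage(list(relative_alpha = 0.5,
                    roi_alpha = c(occipital = 4, parietal = 9,
                                  frontal = 3)), "A2")
  expect_stage(list(relative_alpha = 0.5,
                    roi_alpha = c(occipital = 3, parietal = 5,
                                  frontal = 9)), "A3")
  # ties break toward the posterior regions
  expect_stage(list(relative_alpha = 0.5,
                    roi_alpha = c(occipital = 5, parietal = 5,
                                  frontal = 5)), "A1")
  # low-amplitude beta without SEM -> 0 (score 7); with SEM -> B1 (3)
  beta <- list(relative_alpha = 0.1, slowwave_relative = 0.2)
  expect_stage(beta, "0")
  expect_stage(c(beta, sem_present = TRUE), "B1")
  expect_identical(stage_score("0"), 7L)
  expect_identical(stage_score("B1"), 3L)
  # slow-wave dominance -> B2/3 even with a SEM present
  expect_stage(list(relative_alpha = 0.05, slowwave_relative = 0.8,
                    sem_present = TRUE), "B2/3")
  # graphoelements dominate everything
  expect_stage(list(relative_alpha = 0.9, slowwave_relative = 0.9,
                    roi_alpha = c(occipital = 9, parietal = 1,
                                  frontal = 1),
                    spindle_present = TRUE), "C")
  expect_stage(list(relative_alpha = 0.9,
                    roi_alpha = c(occipital = 9, parietal = 1,
                                  frontal = 1),
                    kcomplex_present = TRUE), "C")
  # alpha below threshold but above zero, no SEM, no slow waves -> 0
  expect_stage(list(relative_alpha = 0.39, slowwave_relative = 0.5), "0")
})

test_that("relative-power staging is invariant to amplitude scaling", {
  rec <- alpha_recording(duration_s = 6)
  cfg <- classifier_config()
  f1 <- segment_features(rec, cfg)
  rec_scaled <- rec
  rec_scaled$data <- rec$data * 7.3
  f2 <- segment_features(rec_scaled, cfg)
  s1 <- vapply(seq_len(nrow(f1)), function(i)
    classify_segment(list(relative_alpha = f1$relative_alpha[i],
                          slowwave_relative = f1$slowwave_relative[i],
                          roi_alpha = c(occipital = f1$occipital_alpha[i],
                                        parietal = f1$parietal_alpha[i],
                                        frontal = f1$frontal_alpha[i]),
                          sem_present = FALSE, spindle_present = FALSE,
                          kcomplex_present = FALSE), cfg), "")
  s2 <- vapply(seq_len(nrow(f2)), function(i)
    classify_segment(list(relative_alpha = f2$relative_alpha[i],
                          slowwave_relative = f2$slowwave_relative[i],
                          roi_alpha = c(occipital = f2$occipital_alpha[i],
                                        parietal = f2$parietal_alpha[i],
                                        frontal = f2$frontal_alpha[i]),
                          sem_present = FALSE, spindle_present = FALSE,
                          kcomplex_present = FALSE), cfg), "")
  expect_identical(s1, s2)
})

test_that("classification is deterministic and honours the artifact mask", {
  script <- make_stage_script("stable_high", duration_s = 60, seed = 4)
  rec <- synthesize_recording(script, seed = 5)
  pp <- preprocess_recording(rec)
  s1 <- classify_recording(pp$rec, pp$mask)
  s2 <- classify_recording(pp$rec, pp$mask)
  expect_identical(s1$stages, s2$stages)
  mask_all <- rep(TRUE, 60)
  s3 <- classify_recording(pp$rec, mask_all)
  expect_true(all(s3$artifact_mask))
})

test_that("without EOG the classifier degrades 0/B1 to 0 with a warning", {
  script <- make_stage_script("custom", duration_s = 60, seed = 1,
                              stages = rep(c("0", "B1"), 30))
  rec <- synthesize_recording(script, seed = 6)
  eeg_only <- recording(rec$subject_id, rec$sfreq,
                        rec$data[rec$channel_roles == "EEG", ],
                        rec$channel_labels[rec$channel_roles == "EEG"])
  pp <- preprocess_recording(eeg_only)
  expect_warning(sq <- classify_recording(pp$rec, pp$mask),
                 "indistinguishable")
  expect_false(any(sq$stages == "B1"))
})
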