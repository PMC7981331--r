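fft_amp <- function(v, sfreq, freq) {
  n <- length(v)
  2 * Mod(stats::fft(v))[round(freq * n / sfreq) + 1] / n
}

test_that("filtering: notch kills 50 Hz, high-pass kills DC, passband intact", {
  sfreq <- 256; n <- 10 * sfreq
  tt <- (seq_len(n) - 1) / sfreq
  mains <- 50 * sin(2 * pi * 50 * tt)
  alpha <- 30 * sin(2 * pi * 10 * tt)
  rec <- recording("f", sfreq,
                   rbind(mains, alpha, 25 + 0 * tt),
                   c("O1", "O2", "Pz"))
  out <- filter_recording(rec)
  mid <- (2 * sfreq):(8 * sfreq)  # avoid filter edges
  atten_db <- 20 * log10(fft_amp(out$data[1, mid], sfreq, 50) /
                         fft_amp(rec$data[1, mid], sfreq, 50))
  expect_lt(atten_db, -20)
  a10 <- fft_amp(out$data[2, mid], sfreq, 10)
  expect_lt(abs(a10 - 30) / 30, 0.05)
  expect_lt(max(abs(out$data[3, mid])), 1)  # DC offset removed
})

test_that("filtering is idempotent in the passband", {
  sfreq <- 256; n <- 8 * sfreq
  tt <- (seq_len(n) - 1) / sfreq
  sig <- 20 * sin(2 * pi * 10 * tt) + 5 * sin(2 * pi * 6 * tt)
  rec <- recording("f", sfreq, rbind(sig, sig), c("O1", "O2"))
  once <- filter_recording(rec)
  twice <- filter_recording(once)
  mid <- (2 * sfreq):(6 * sfreq)
  expect_lt(max(abs(once$data[1, mid] - twice$data[1, mid])) /
              stats::sd(once$data[1, mid]), 0.05)
})

test_that("EOG channels keep sub-0.5 Hz content that EEG loses", {
  sfreq <- 256; n <- 40 * sfreq
  tt <- (seq_len(n) - 1) / sfreq
  slow <- 50 * sin(2 * pi * 0.25 * tt)
  rec <- recording("s", sfreq, rbind(slow, slow, slow),
                   c("O1", "O2", "HEOGL"))
  out <- filter_recording(rec)
  mid <- (10 * sfreq):(30 * sfreq)
  eeg_amp <- fft_amp(out$data[1, mid], sfreq, 0.25)
  eog_amp <- fft_amp(out$data[3, mid], sfreq, 0.25)
  expect_gt(eog_amp, 40)        # SEM band survives on EOG
  expect_lt(eeg_amp, eog_amp / 2)  # EEG high-pass attenuates it
})

test_that("common average reference zeroes the cross-channel mean", {
  # already zero-mean pair is unchanged
  d <- rbind(c(5, 5, 5), c(-5, -5, -5))
  rec <- recording("c", 100, d, c("C3", "C4"))
  expect_equal(common_average(rec)$data, rec$data,
               ignore_attr = TRUE)
  rec2 <- recording("c", 100, rbind(c(10, 10), c(0, 0)), c("C3", "C4"))
  expect_equal(unname(common_average(rec2)$data),
               rbind(c(5, 5), c(-5, -5)))
  set.seed(1)
  rec3 <- recording("c", 100, matrix(rnorm(31 * 50), 31, 50),
                    arousalstrat:::.SYNTH_CHANNELS)
  car <- common_average(rec3)
  expect_lt(max(abs(colMeans(car$data))), 1e-9)
  # EOG channels are untouched
  rec4 <- recording("c", 100, rbind(c(10, 10), c(0, 0), c(7, 7)),
                    c("C3", "C4", "HEOGL"))
  expect_equal(unname(common_average(rec4)$data[3, ]), c(7, 7))
  expect_error(common_average(recording("c", 100, matrix(0, 1, 5), "Cz")),
               "at least 2")
})

test_that("artifact mask flags exactly the segments with large peaks", {
  sfreq <- 128
  rec <- alpha_recording(duration_s = 10, sfreq = sfreq)
  cfg <- preprocess_config()
  expect_false(any(artifact_mask(rec, cfg)))  # clean 20/40 uV alpha
  # 500 uV transient inside segment 7 only
  rec$data[1, 6 * sfreq + 50] <- 500
  mask <- artifact_mask(rec, cfg)
  expect_identical(which(mask), 7L)
  # degenerate zero threshold flags everything
  cfg0 <- preprocess_config(artifact_amp_uv = 0)
  expect_true(all(artifact_mask(rec, cfg0)))
})

test_that("usability rule: exclusion only strictly above 15%", {
  cfg <- preprocess_config()
  expect_true(check_usable(rep(c(TRUE, FALSE), c(135, 765)), cfg))
  expect_false(check_usable(rep(c(TRUE, FALSE), c(136, 764)), cfg))
  expect_true(check_usable(rep(FALSE, 900), cfg))
  expect_error(check_usable(logical(0), cfg), "empty")
  # monotone: adding flagged segments never rescues a recording
  set.seed(2)
  mask <- runif(900) < 0.2
  for (i in 1:20) {
    if (check_usable(mask, cfg)) break
    mask2 <- mask; mask2[sample(which(!mask2), 1)] <- TRUE
    expect_false(check_usable(mask2, cfg) && !check_usable(mask, cfg))
    mask <- mask2
  }
})

test_that("segmentation floors to whole seconds and validates duration", {
  rec <- recording("s", 256, matrix(0, 2, round(900.7 * 256)),
                   c("O1", "O2"))
  win <- segment_windows(rec)
  expect_equal(nrow(win), 900)
  expect_equal(win$start[1], 1)
  expect_equal(win$end[900], 900 * 256)
  # no overlap, full coverage up to the discarded remainder
  expect_true(all(win$start[-1] == head(win$end, -1) + 1))
  rec1 <- recording("s", 256, matrix(0, 2, 256), c("O1", "O2"))
  expect_equal(nrow(segment_windows(rec1)), 1)
  rec_half <- recording("s", 256, matrix(0, 2, 128), c("O1", "O2"))
  expect_error(segment_windows(rec_half), "shorter")
})

test_that("config validation rejects impossible corner settings", {
  expect_error(preprocess_config(highpass_hz = 80, lowpass_hz = 70),
               "highpass")
  expect_error(preprocess_config(max_artifact_fraction = 1.5),
               "max_artifact_fraction")
  rec <- recording("s", 100, matrix(0, 2, 500), c("O1", "O2"))
  expect_error(filter_recording(rec), "too low")
})
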