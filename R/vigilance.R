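#' Vigilance classifier configuration
#'
#' Thresholds and regions used to assign one of the seven vigilance
#' stages to each 1-s segment. The stage criteria are spectral
#' (delta/theta/alpha/beta band powers, alpha topography over
#' occipital/parietal/frontal regions), ocular (horizontal slow eye
#' movements, SEMs) and graphoelement-based (sleep spindles and
#' K-complexes). All numeric thresholds are this package's calibrated
#' choices and are configurable; relative (scale-invariant) alpha and
#' slow-wave thresholds are used rather than absolute amplitudes.
#'
#' @param roi Named list of electrode labels per region (occipital,
#'   parietal, frontal).
#' @param frontocentral Electrode labels scanned for spindles and
#'   K-complexes.
#' @param alpha_rel_min Minimum relative alpha (alpha / total band power
#'   in the alpha-maximal region) for an A stage (default 0.40).
#' @param slowwave_rel_min Minimum relative slow-wave power
#'   ((delta+theta)/total across EEG channels) for B2/3 (default 0.55).
#' @param sem_amp_uv Minimum SEM deflection amplitude in the 0.1-1 Hz
#'   band-passed horizontal EOG (default 25).
#' @param sem_band_hz SEM band edges (default c(0.1, 1)).
#' @param sem_min_duration_s Minimum monotone deflection duration
#'   (default 0.5).
#' @param spindle_band_hz Spindle band (default c(11, 16)).
#' @param spindle_env_factor Spindle envelope threshold as a multiple of
#'   the subject's median envelope (default 3).
#' @param spindle_min_amp_uv Absolute envelope floor for spindle events
#'   (default 15), guarding against a degenerate median baseline in
#'   recordings with little sigma-band background.
#' @param spindle_min_duration_s Minimum supra-threshold duration
#'   (default 0.5).
#' @param kcomplex_p2p_uv Minimum K-complex peak-to-peak amplitude
#'   (default 100).
#' @param kcomplex_window_s Admissible duration range of the biphasic
#'   deflection (default c(0.5, 1.5)).
#' @param bands Band edges in Hz, half-open [lo, hi).
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(
    roi = list(occipital = c("O1", "O2"),
               parietal = c("P3", "P4", "Pz"),
               frontal = c("F3", "F4", "Fz")),
    frontocentral = c("Fz", "FC1", "FC2", "Cz", "C3", "C4"),
    alpha_rel_min = 0.40, slowwave_rel_min = 0.55,
    sem_amp_uv = 25, sem_band_hz = c(0.1, 1), sem_min_duration_s = 0.5,
    spindle_band_hz = c(11, 16), spindle_env_factor = 3,
    spindle_min_amp_uv = 15, spindle_min_duration_s = 0.5,
    kcomplex_p2p_uv = 100, kcomplex_window_s = c(0.5, 1.5),
    bands = list(delta = c(2, 4), theta = c(4, 7),
                 alpha = c(8, 12), beta = c(12, 25))) {
  stopifnot(alpha_rel_min > 0, slowwave_rel_min > 0, sem_amp_uv > 0,
            spindle_env_factor > 0, kcomplex_p2p_uv > 0)
  structure(as.list(environment()), class = "classifier_config")
}

#' Band powers of a single 1-s segment
#'
#' Hann-tapered periodogram at 1 Hz resolution; a band's power is the
#' sum over bins whose centre frequency lies in [lo, hi). Scaled so a
#' pure sinusoid of amplitude A contributes approximately A^2/2 to its
#' band (microvolt^2).
#'
#' @param segment Channels x samples matrix (exactly 1 s of data) or a
#'   single-channel numeric vector.
#' @param sfreq Sampling rate in Hz (>= 64).
#' @param bands Named list of band edges.
#' @return Channels x bands matrix of band powers.
#' @export
band_powers <- function(segment, sfreq,
                        bands = classifier_config()$bands) {
  if (is.null(dim(segment))) segment <- matrix(segment, nrow = 1)
  if (sfreq < 64) stop("sfreq must be >= 64 Hz", call. = FALSE)
  if (ncol(segment) != round(sfreq)) {
    stop("segment must be exactly 1 s long (", round(sfreq), " samples)",
         call. = FALSE)
  }
  .band_power_matrix(segment, sfreq, bands)
}

# channels x samples -> channels x bands, vectorised over channels
.band_power_matrix <- function(m, sfreq, bands) {
  n <- ncol(m)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)  # Hann taper
  S <- sum(w)
  enbw <- n * sum(w^2) / S^2  # leakage correction for band sums
  X <- stats::mvfft(t(m * rep(w, each = nrow(m))))
  P <- 2 * Mod(X)^2 / (S^2 * enbw)                   # bins x channels
  freqs <- (seq_len(n) - 1) * sfreq / n
  out <- vapply(bands, function(b) {
    sel <- freqs >= b[1] & freqs < b[2] & freqs <= sfreq / 2
    colSums(P[sel, , drop = FALSE])
  }, numeric(nrow(m)))
  if (nrow(m) == 1L) out <- matrix(out, nrow = 1,
                                   dimnames = list(NULL, names(bands)))
  rownames(out) <- rownames(m)
  out
}

# band powers for every segment of a recording: list of arrays
# [channel, band] per segment — computed with one FFT batch per channel
.recording_band_powers <- function(rec, windows, bands) {
  spp <- windows$end[1] - windows$start[1] + 1L
  n_seg <- nrow(windows)
  n <- spp
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
  S <- sum(w)
  enbw <- n * sum(w^2) / S^2
  freqs <- (seq_len(n) - 1) * rec$sfreq / n
  sel <- lapply(bands, function(b)
    freqs >= b[1] & freqs < b[2] & freqs <= rec$sfreq / 2)
  eeg_idx <- .eeg_channels(rec)
  res <- array(0, dim = c(length(eeg_idx), length(bands), n_seg),
               dimnames = list(rec$channel_labels[eeg_idx], names(bands),
                               NULL))
  for (ci in seq_along(eeg_idx)) {
    v <- rec$data[eeg_idx[ci], seq_len(n_seg * spp)]
    segm <- matrix(v, nrow = spp) * w          # samples x segments
    P <- 2 * Mod(stats::mvfft(segm))^2 / (S^2 * enbw)
    for (bi in seq_along(bands)) {
      res[ci, bi, ] <- colSums(P[sel[[bi]], , drop = FALSE])
    }
  }
  res
}

#' Horizontal EOG derivation
#'
#' Difference of the two horizontal (canthus) EOG channels, or the
#' single horizontal channel if only one exists.
#'
#' @param rec An `eeg_recording`.
#' @return Numeric vector, or NULL when no horizontal EOG channel exists.
#' @export
horizontal_eog <- function(rec) {
  idx <- which(rec$channel_roles == "EOG-horizontal")
  if (length(idx) == 0L) return(NULL)
  if (length(idx) == 1L) return(rec$data[idx, ])
  rec$data[idx[1], ] - rec$data[idx[2], ]
}

# monotone deflection events in a band-passed slow signal:
# data frame of (start, end) sample indices of deflections whose
# amplitude and duration clear the SEM thresholds
.sem_events <- function(eog, sfreq, cfg) {
  nyq <- sfreq / 2
  bp <- signal::butter(2, cfg$sem_band_hz / nyq, type = "pass")
  v <- signal::filtfilt(bp, eog)
  d <- sign(diff(v))
  d[d == 0] <- NA
  # carry forward the last nonzero slope so plateaus join their run
  if (all(is.na(d))) return(data.frame(start = integer(), end = integer()))
  d <- zoo_na_locf(d)
  runs <- rle(d)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  keep <- logical(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i] + 1L   # diff index -> sample index
    amp <- abs(v[e] - v[s])
    dur <- (e - s) / sfreq
    keep[i] <- amp >= cfg$sem_amp_uv && dur >= cfg$sem_min_duration_s
  }
  data.frame(start = starts[keep], end = ends[keep] + 1L)
}

# last-observation-carried-forward for the slope sign (leading NAs get
# the first observed value)
zoo_na_locf <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- cummax(ifelse(ok, seq_along(x), 0L))
  idx[idx == 0L] <- which(ok)[1]
  x[idx]
}

#' Detect slow eye movements
#'
#' A SEM is a monotone deflection of the 0.1-1 Hz band-passed horizontal
#' EOG exceeding `sem_amp_uv` and lasting at least
#' `sem_min_duration_s`. With `windows` supplied, returns one logical
#' per segment (TRUE when a SEM overlaps that segment); otherwise a
#' single logical for the whole trace (intended use: a segment with
#' +/- 1 s of context).
#'
#' @param eog Horizontal EOG trace in microvolts.
#' @param sfreq Sampling rate.
#' @param cfg A [classifier_config()].
#' @param windows Optional [segment_windows()] data frame.
#' @return Logical scalar or vector.
#' @export
detect_sem <- function(eog, sfreq, cfg = classifier_config(),
                       windows = NULL) {
  if (is.null(eog)) {
    stop("no horizontal EOG derivation available: SEM detection impossible",
         call. = FALSE)
  }
  ev <- .sem_events(eog, sfreq, cfg)
  if (is.null(windows)) return(nrow(ev) > 0L)
  .events_to_segments(ev, windows)
}

.events_to_segments <- function(ev, windows) {
  out <- logical(nrow(windows))
  if (nrow(ev) == 0L) return(out)
  for (i in seq_len(nrow(ev))) {
    hit <- windows$start <= ev$end[i] & windows$end >= ev$start[i]
    out <- out | hit
  }
  out
}

.hilbert_env <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# supra-threshold runs of a vector: data frame of start/end indices of
# maximal runs where x > thr lasting >= min_len samples
.runs_above <- function(x, thr, min_len) {
  r <- rle(x > thr)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

#' Detect sleep graphoelements (spindles and K-complexes)
#'
#' Spindle: the Hilbert envelope of the 11-16 Hz band-passed signal on
#' any fronto-central channel exceeds `spindle_env_factor` times that
#' channel's median envelope for at least `spindle_min_duration_s`.
#' K-complex: a biphasic deflection of the 0.5-4 Hz band-passed signal —
#' two successive opposite extrema with peak-to-peak amplitude of at
#' least `kcomplex_p2p_uv` — whose total duration (twice the extremum
#' separation, for the roughly symmetric biphasic shape) falls within
#' `kcomplex_window_s`.
#'
#' @param rec A preprocessed `eeg_recording` (or channels x samples
#'   matrix of fronto-central channels).
#' @param cfg A [classifier_config()].
#' @param windows Optional [segment_windows()]; when supplied the result
#'   is per segment.
#' @param sfreq Required when `rec` is a bare matrix.
#' @return List with logical `spindle` and `kcomplex` (scalar, or one
#'   element per segment when `windows` is given).
#' @export
detect_graphoelements <- function(rec, cfg = classifier_config(),
                                  windows = NULL, sfreq = NULL) {
  if (inherits(rec, "eeg_recording")) {
    labs <- intersect(cfg$frontocentral, rec$channel_labels)
    if (length(labs) == 0L) {
      stop("no fronto-central channels present for graphoelement detection",
           call. = FALSE)
    }
    m <- rec$data[labs, , drop = FALSE]
    sfreq <- rec$sfreq
  } else {
    m <- if (is.null(dim(rec))) matrix(rec, nrow = 1) else as.matrix(rec)
    if (is.null(sfreq)) stop("sfreq required for matrix input", call. = FALSE)
  }
  nyq <- sfreq / 2
  sp_filt <- signal::butter(4, cfg$spindle_band_hz / nyq, type = "pass")
  kc_filt <- signal::butter(2, c(0.5, 4) / nyq, type = "pass")
  sp_ev <- data.frame(start = integer(), end = integer())
  kc_ev <- sp_ev
  min_len <- round(cfg$spindle_min_duration_s * sfreq)
  for (i in seq_len(nrow(m))) {
    env <- .hilbert_env(signal::filtfilt(sp_filt, m[i, ]))
    # relative criterion with an absolute floor: the median-envelope
    # baseline under-estimates background when most of the recording
    # carries little sigma-band activity
    thr <- max(cfg$spindle_env_factor * stats::median(env),
               cfg$spindle_min_amp_uv)
    sp_ev <- rbind(sp_ev, .runs_above(env, thr, min_len))
    kc_ev <- rbind(kc_ev, .kcomplex_events(signal::filtfilt(kc_filt, m[i, ]),
                                           sfreq, cfg))
  }
  if (is.null(windows)) {
    list(spindle = nrow(sp_ev) > 0L, kcomplex = nrow(kc_ev) > 0L)
  } else {
    list(spindle = .events_to_segments(sp_ev, windows),
         kcomplex = .events_to_segments(kc_ev, windows))
  }
}

.kcomplex_events <- function(v, sfreq, cfg) {
  d <- sign(diff(v))
  d[d == 0] <- NA
  d <- zoo_na_locf(d)
  turn <- which(diff(d) != 0) + 1L   # local extremum sample indices
  out <- data.frame(start = integer(), end = integer())
  if (length(turn) < 2L) return(out)
  for (i in seq_len(length(turn) - 1L)) {
    a <- turn[i]; b <- turn[i + 1L]
    p2p <- abs(v[b] - v[a])
    dur <- 2 * (b - a) / sfreq
    if (p2p >= cfg$kcomplex_p2p_uv &&
        dur >= cfg$kcomplex_window_s[1] && dur <= cfg$kcomplex_window_s[2]) {
      out <- rbind(out, data.frame(start = a, end = b))
    }
  }
  out
}

#' Classify one segment from its features
#'
#' Decision order: (1) a spindle or K-complex forces stage C;
#' (2) otherwise dominant slow-wave activity without alpha gives B2/3;
#' (3) otherwise sufficient relative alpha gives an A stage, sub-staged
#' by the alpha-maximal region (occipital A1, parietal A2, frontal A3;
#' ties resolved occipital > parietal > frontal); (4) otherwise a SEM
#' gives B1; (5) otherwise stage 0.
#'
#' @param features List with `relative_alpha`, `slowwave_relative`,
#'   `roi_alpha` (named numeric: occipital, parietal, frontal),
#'   `sem_present`, `spindle_present`, `kcomplex_present`.
#' @param cfg A [classifier_config()].
#' @return Stage name (character scalar).
#' @export
classify_segment <- function(features, cfg = classifier_config()) {
  f <- features
  if (isTRUE(f$spindle_present) || isTRUE(f$kcomplex_present)) return("C")
  if (f$slowwave_relative >= cfg$slowwave_rel_min &&
      f$relative_alpha < cfg$alpha_rel_min) return("B2/3")
  if (f$relative_alpha >= cfg$alpha_rel_min) {
    ra <- f$roi_alpha[c("occipital", "parietal", "frontal")]
    return(c("A1", "A2", "A3")[which.max(ra)])  # which.max: first = tie win
  }
  if (isTRUE(f$sem_present)) return("B1")
  "0"
}

#' Per-segment features of a preprocessed recording
#'
#' @param rec A preprocessed `eeg_recording`.
#' @param cfg A [classifier_config()].
#' @param windows Optional [segment_windows()].
#' @return Data frame, one row per segment, with the spectral and event
#'   features used by [classify_segment()].
#' @export
segment_features <- function(rec, cfg = classifier_config(),
                             windows = segment_windows(rec)) {
  bp <- .recording_band_powers(rec, windows, cfg$bands)  # ch x band x seg
  labs <- dimnames(bp)[[1]]
  roi_idx <- lapply(cfg$roi, function(chs) {
    idx <- match(intersect(chs, labs), labs)
    if (length(idx) == 0L) {
      stop("channel set lacks a configured region of interest",
           call. = FALSE)
    }
    idx
  })
  n_seg <- dim(bp)[3]
  band_m <- function(band, idx = seq_along(labs)) {
    # channels x segments matrix for one band (robust to length-1 idx)
    matrix(bp[idx, band, , drop = FALSE], ncol = n_seg)
  }
  total <- band_m("delta") + band_m("theta") + band_m("alpha") +
    band_m("beta")
  roi_alpha <- vapply(roi_idx, function(idx)
    colMeans(band_m("alpha", idx)), numeric(n_seg))
  roi_total <- vapply(roi_idx, function(idx)
    colMeans(matrix(total[idx, ], ncol = n_seg)), numeric(n_seg))
  roi_alpha <- matrix(roi_alpha, ncol = length(roi_idx),
                      dimnames = list(NULL, names(roi_idx)))
  roi_total <- matrix(roi_total, ncol = length(roi_idx),
                      dimnames = list(NULL, names(roi_idx)))
  max_roi <- max.col(roi_alpha, ties.method = "first")
  rel_alpha <- roi_alpha[cbind(seq_len(n_seg), max_roi)] /
    pmax(roi_total[cbind(seq_len(n_seg), max_roi)], .Machine$double.eps)
  slowwave <- colMeans(band_m("delta") + band_m("theta")) /
    pmax(colMeans(total), .Machine$double.eps)

  heog <- horizontal_eog(rec)
  sem <- if (is.null(heog)) rep(NA, n_seg) else
    detect_sem(heog, rec$sfreq, cfg, windows)
  gr <- detect_graphoelements(rec, cfg, windows)

  data.frame(segment = windows$segment,
             occipital_alpha = roi_alpha[, "occipital"],
             parietal_alpha = roi_alpha[, "parietal"],
             frontal_alpha = roi_alpha[, "frontal"],
             relative_alpha = rel_alpha,
             slowwave_relative = slowwave,
             sem_present = sem,
             spindle_present = gr$spindle,
             kcomplex_present = gr$kcomplex)
}

#' Classify every segment of a recording
#'
#' Runs the full per-segment feature extraction and staging. When the
#' recording has no horizontal EOG the classifier degrades: stages 0 and
#' B1 cannot be distinguished, both map to "0", and a warning is issued.
#' Artifact-flagged segments keep their mask bit and carry stage "0" as
#' a placeholder that downstream code must ignore.
#'
#' @param rec A preprocessed `eeg_recording` (see
#'   [preprocess_recording()]).
#' @param mask Logical artifact mask (default: no artifacts).
#' @param cfg A [classifier_config()].
#' @return A [stage_sequence()].
#' @export
classify_recording <- function(rec, mask = NULL,
                               cfg = classifier_config()) {
  windows <- segment_windows(rec)
  if (is.null(mask)) mask <- rep(FALSE, nrow(windows))
  if (length(mask) != nrow(windows)) {
    stop("mask length must equal segment count", call. = FALSE)
  }
  feats <- segment_features(rec, cfg, windows)
  degraded <- all(is.na(feats$sem_present))
  if (degraded) {
    warning("no horizontal EOG: stages 0 and B1 are indistinguishable; ",
            "both reported as \"0\"", call. = FALSE)
    feats$sem_present <- FALSE
  }
  stages <- vapply(seq_len(nrow(feats)), function(i) {
    classify_segment(list(
      relative_alpha = feats$relative_alpha[i],
      slowwave_relative = feats$slowwave_relative[i],
      roi_alpha = c(occipital = feats$occipital_alpha[i],
                    parietal = feats$parietal_alpha[i],
                    frontal = feats$frontal_alpha[i]),
      sem_present = feats$sem_present[i],
      spindle_present = feats$spindle_present[i],
      kcomplex_present = feats$kcomplex_present[i]), cfg)
  }, "")
  stages[mask] <- "0"  # placeholder under the artifact bit
  stage_sequence(rec$subject_id, stages, mask)
}
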