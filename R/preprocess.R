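#' Preprocessing configuration
#'
#' Filter corners and artifact rules applied before vigilance staging.
#' EEG channels are band-limited `highpass_hz`-`lowpass_hz` with a notch
#' at `notch_hz` +/- `notch_halfwidth_hz`; EOG channels are high-passed
#' at the lower `eog_highpass_hz` instead so slow eye movements (< 1 Hz)
#' survive. A 1-s segment is flagged artifactual when any EEG channel
#' exceeds `artifact_amp_uv` peak amplitude; recordings with more than
#' `max_artifact_fraction` flagged segments are unusable.
#'
#' @param highpass_hz EEG high-pass corner (default 0.5 Hz).
#' @param lowpass_hz Low-pass corner (default 70 Hz).
#' @param notch_hz Mains notch centre (default 50 Hz).
#' @param notch_halfwidth_hz Notch half width (default 2 Hz).
#' @param eog_highpass_hz EOG high-pass corner (default 0.1 Hz).
#' @param artifact_amp_uv Peak-amplitude artifact threshold (default 100).
#' @param max_artifact_fraction Exclusion threshold on the flagged
#'   fraction (default 0.15; exclusion is strictly greater).
#' @param segment_len_s Segment length in seconds (default 1).
#' @return List of class `preprocess_config`.
#' @export
preprocess_config <- function(highpass_hz = 0.5, lowpass_hz = 70,
                              notch_hz = 50, notch_halfwidth_hz = 2,
                              eog_highpass_hz = 0.1, artifact_amp_uv = 100,
                              max_artifact_fraction = 0.15,
                              segment_len_s = 1) {
  if (!(highpass_hz > 0 && highpass_hz < lowpass_hz)) {
    stop("need 0 < highpass_hz < lowpass_hz", call. = FALSE)
  }
  if (!(max_artifact_fraction > 0 && max_artifact_fraction < 1)) {
    stop("max_artifact_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
                 notch_hz = notch_hz, notch_halfwidth_hz = notch_halfwidth_hz,
                 eog_highpass_hz = eog_highpass_hz,
                 artifact_amp_uv = artifact_amp_uv,
                 max_artifact_fraction = max_artifact_fraction,
                 segment_len_s = segment_len_s),
            class = "preprocess_config")
}

#' Band-limit a recording
#'
#' Zero-phase (forward-backward Butterworth) filtering: EEG channels get
#' high-pass, low-pass and mains notch; EOG channels get the low-pass and
#' notch but a lower high-pass corner to preserve slow eye movements.
#'
#' @param rec An `eeg_recording`.
#' @param cfg A [preprocess_config()].
#' @return The filtered recording.
#' @export
filter_recording <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sfreq / 2
  if (cfg$lowpass_hz >= nyq) {
    stop("sampling rate too low for requested low-pass (need sfreq > 2*",
         cfg$lowpass_hz, " Hz)", call. = FALSE)
  }
  lp <- signal::butter(4, cfg$lowpass_hz / nyq, type = "low")
  hp_eeg <- signal::butter(2, cfg$highpass_hz / nyq, type = "high")
  hp_eog <- signal::butter(2, cfg$eog_highpass_hz / nyq, type = "high")
  notch <- signal::butter(2, c(cfg$notch_hz - cfg$notch_halfwidth_hz,
                               cfg$notch_hz + cfg$notch_halfwidth_hz) / nyq,
                          type = "stop")
  is_eeg <- rec$channel_roles == "EEG"
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    v <- signal::filtfilt(lp, out[i, ])
    v <- signal::filtfilt(notch, v)
    v <- signal::filtfilt(if (is_eeg[i]) hp_eeg else hp_eog, v)
    out[i, ] <- v
  }
  rec$data <- out
  rec
}

#' Re-reference EEG channels to the common average
#'
#' Subtracts, at every sample, the mean across EEG channels from each EEG
#' channel; EOG channels are untouched.
#'
#' @param rec An `eeg_recording` with at least 2 EEG channels.
#' @return The re-referenced recording.
#' @export
common_average <- function(rec) {
  idx <- .eeg_channels(rec)
  if (length(idx) < 2L) {
    stop("common-average reference needs at least 2 EEG channels",
         call. = FALSE)
  }
  avg <- colMeans(rec$data[idx, , drop = FALSE])
  rec$data[idx, ] <- sweep(rec$data[idx, , drop = FALSE], 2, avg)
  rec
}

#' Segment boundaries for a recording
#'
#' Non-overlapping half-open 1-s windows; a trailing partial second is
#' discarded.
#'
#' @param rec An `eeg_recording`.
#' @param cfg A [preprocess_config()].
#' @return Data frame with columns `segment` (1-based), `start`, `end`
#'   (sample indices, inclusive).
#' @export
segment_windows <- function(rec, cfg = preprocess_config()) {
  spp <- round(cfg$segment_len_s * rec$sfreq)
  n_seg <- floor(ncol(rec$data) / spp)
  if (n_seg < 1L) {
    stop("recording shorter than one segment (", cfg$segment_len_s, " s)",
         call. = FALSE)
  }
  data.frame(segment = seq_len(n_seg),
             start = (seq_len(n_seg) - 1L) * spp + 1L,
             end = seq_len(n_seg) * spp)
}

#' Peak-amplitude artifact mask
#'
#' Flags a segment when any EEG channel's peak absolute amplitude within
#' it exceeds the threshold. A deterministic surrogate for visual
#' artifact inspection.
#'
#' @param rec A filtered `eeg_recording`.
#' @param cfg A [preprocess_config()].
#' @return Logical vector, one element per segment (TRUE = artifact).
#' @export
artifact_mask <- function(rec, cfg = preprocess_config()) {
  win <- segment_windows(rec, cfg)
  eeg <- rec$data[.eeg_channels(rec), , drop = FALSE]
  vapply(seq_len(nrow(win)), function(i) {
    any(abs(eeg[, win$start[i]:win$end[i]]) > cfg$artifact_amp_uv)
  }, logical(1))
}

#' Is a recording usable under the artifact-fraction rule?
#'
#' Unusable iff the flagged fraction is strictly greater than
#' `max_artifact_fraction` (a recording at exactly the threshold is
#' kept).
#'
#' @param mask Logical artifact mask.
#' @param cfg A [preprocess_config()].
#' @return Logical.
#' @export
check_usable <- function(mask, cfg = preprocess_config()) {
  if (length(mask) == 0L) stop("empty artifact mask", call. = FALSE)
  mean(mask) <= cfg$max_artifact_fraction
}

#' Filter, re-reference and mask a recording in one step
#'
#' @param rec A raw `eeg_recording`.
#' @param cfg A [preprocess_config()].
#' @return List with `rec` (preprocessed), `mask`, `usable`.
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config()) {
  rec <- filter_recording(rec, cfg)
  rec <- common_average(rec)
  mask <- artifact_mask(rec, cfg)
  list(rec = rec, mask = mask, usable = check_usable(mask, cfg))
}
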