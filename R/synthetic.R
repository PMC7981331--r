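#' @name synthetic_data
#' @title Synthetic EEG and cohort generation
#' @description
#' Ground-truth generators used to exercise the pipeline end to end:
#' per-second vigilance stage scripts with named trajectory profiles,
#' multichannel EEG+EOG recordings whose per-second spectral and event
#' content matches the scripted stage, and cohort questionnaire tables
#' whose group-level scale means/SDs follow the study's descriptive
#' statistics (n = 78 non-hypoaroused / 24 hypoaroused by default).
NULL

.SYNTH_CHANNELS <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                     "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4",
                     "T8", "CP5", "CP1", "CP2", "CP6", "TP9", "TP10",
                     "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "O2",
                     "PO10")
.SYNTH_EOG <- c("HEOGL", "HEOGR", "VEOGU", "VEOGD")

.with_seed <- function(seed, expr) {
  force(seed)  # before the state capture: the promise may draw from the RNG
  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Build a per-second vigilance stage script
#'
#' Profiles: `stable_high` — an A1/0-dominated walk with no B or C
#' stages, so the realised stability score is 10 or 11 by construction;
#' `declining` — a staged descent A1 -> A2 -> A3 -> B1 -> B2/3 with a
#' C-containing tail (stochastic dwell times); `fluctuating` — runs
#' alternating between A stages and B1/B2/3 without C; `custom` — the
#' caller supplies `stages`. The realised script's true stability score
#' is computed with [stability_score()] and returned alongside.
#'
#' @param profile One of "stable_high", "declining", "fluctuating",
#'   "custom".
#' @param duration_s Script length in seconds (>= 60; default 900).
#' @param seed Integer seed.
#' @param c_onset_s For "declining": force the first C stage to this
#'   many seconds from the start (NULL = stochastic).
#' @param stages For "custom": character vector of stage names.
#' @return List of class `stage_script`: `stages`, `profile`, `seed`,
#'   `true_score`.
#' @export
make_stage_script <- function(profile = c("stable_high", "declining",
                                          "fluctuating", "custom"),
                              duration_s = 900, seed = 1,
                              c_onset_s = NULL, stages = NULL) {
  if (length(profile) == 1L && !profile %in% c("stable_high", "declining",
                                               "fluctuating", "custom")) {
    stop("unknown stage-script profile: ", profile, call. = FALSE)
  }
  profile <- match.arg(profile)
  if (duration_s < 60) stop("duration_s must be >= 60", call. = FALSE)
  out <- .with_seed(seed, {
    switch(profile,
      stable_high = .script_markov(
        duration_s, states = c("A1", "0", "A2"),
        probs = c(0.7, 0.15, 0.15), mean_dwell = 20),
      fluctuating = .script_markov(
        duration_s, states = c("A1", "B1", "B2/3", "A2"),
        probs = c(0.45, 0.25, 0.2, 0.1), mean_dwell = 15),
      declining = .script_declining(duration_s, c_onset_s),
      custom = {
        if (is.null(stages)) {
          stop("custom profile requires `stages`", call. = FALSE)
        }
        if (length(stages) != duration_s) {
          stop("custom stages length must equal duration_s", call. = FALSE)
        }
        as.character(stages)
      })
  })
  structure(list(stages = out, profile = profile, seed = seed,
                 true_score = stability_score(out)$score),
            class = "stage_script")
}

.script_markov <- function(duration_s, states, probs, mean_dwell) {
  out <- character(0)
  last <- NA
  while (length(out) < duration_s) {
    s <- sample(states, 1, prob = probs)
    if (identical(s, last)) next
    dwell <- 1 + stats::rgeom(1, 1 / mean_dwell)
    out <- c(out, rep(s, dwell))
    last <- s
  }
  out[seq_len(duration_s)]
}

.script_declining <- function(duration_s, c_onset_s) {
  phases <- c("A1", "A2", "A3", "B1", "B2/3")
  dwell <- pmax(20, round(stats::rnorm(5, mean = c(150, 90, 60, 90, 120),
                                       sd = c(50, 30, 20, 30, 40))))
  onset <- if (is.null(c_onset_s)) sum(dwell) else round(c_onset_s)
  if (!is.null(c_onset_s)) {
    dwell <- pmax(1, round(dwell * (onset / sum(dwell))))
    # trim/pad the last phase so the descent ends exactly at onset
    dwell[5] <- max(1, dwell[5] + onset - sum(dwell))
  }
  onset <- min(onset, duration_s - 1)
  head_part <- rep(phases, times = dwell)[seq_len(min(sum(dwell), onset))]
  if (length(head_part) < onset) {
    head_part <- c(head_part, rep("B2/3", onset - length(head_part)))
  }
  tail_len <- duration_s - onset
  # C-containing tail: short C runs embedded in B2/3
  tail_part <- character(0)
  while (length(tail_part) < tail_len) {
    tail_part <- c(tail_part,
                   rep("C", 1 + stats::rgeom(1, 1 / 3)),
                   rep("B2/3", 1 + stats::rgeom(1, 1 / 6)))
  }
  c(head_part, tail_part[seq_len(tail_len)])
}

# ---------------------------------------------------------------------------
# signal synthesis

.band_noise <- function(n_ch, n, sfreq, band, rms) {
  lo <- max(band[1], 1e-3); hi <- min(band[2], sfreq / 2 - 1e-6)
  bp <- signal::butter(2, c(lo, hi) / (sfreq / 2), type = "pass")
  m <- matrix(stats::rnorm(n_ch * n), nrow = n_ch)
  for (i in seq_len(n_ch)) {
    v <- signal::filtfilt(bp, m[i, ])
    s <- stats::sd(v)
    m[i, ] <- if (s > 0) v * (rms / s) else v
  }
  m
}

.pink_noise <- function(n_ch, n, rms) {
  # spectral synthesis: white spectrum shaped by 1/sqrt(f)
  m <- matrix(0, n_ch, n)
  f <- c(1, seq_len(n - 1))
  shape <- 1 / sqrt(pmin(f, n - f + 1))
  for (i in seq_len(n_ch)) {
    X <- stats::fft(stats::rnorm(n)) * shape
    v <- Re(stats::fft(X, inverse = TRUE) / n)
    m[i, ] <- v * (rms / stats::sd(v))
  }
  m
}

#' Synthesise a multichannel EEG recording from a stage script
#'
#' Per second the signal carries the scripted stage's content: stage 0 —
#' low-amplitude 12-25 Hz broadband; A1/A2/A3 — a 10 Hz alpha rhythm
#' maximal (2:1 amplitude gradient) over the occipital/parietal/frontal
#' region respectively, on a pink-noise floor; B1 — stage-0 spectrum
#' plus a 0.25 Hz, 60 uV slow-eye-movement waveform on the horizontal
#' EOG pair; B2/3 — 2-6 Hz dominated activity; C — slow background plus
#' one graphoelement per second (alternating a 13 Hz, 0.8 s spindle and
#' a biphasic K-complex on fronto-central channels). Oscillation phase
#' is continuous across the seconds of a stage run.
#'
#' @param script A [make_stage_script()] result (or character vector of
#'   stages).
#' @param sfreq Sampling rate (default 256 Hz; the study's 1 kHz is
#'   supported).
#' @param channels EEG channel labels (default: a 31-electrode extended
#'   10-20 set).
#' @param seed Integer seed.
#' @param noise_uv RMS of the additive broadband sensor noise
#'   (default 2).
#' @param subject_id Subject identifier.
#' @return An [recording()] with 4 EOG channels appended.
#' @export
synthesize_recording <- function(script, sfreq = 256,
                                 channels = .SYNTH_CHANNELS, seed = 1,
                                 noise_uv = 2, subject_id = "synth") {
  stages <- if (inherits(script, "stage_script")) script$stages else
    as.character(script)
  cfg <- classifier_config()
  for (r in names(cfg$roi)) {
    if (!any(cfg$roi[[r]] %in% channels)) {
      stop("channel set lacks the ", r, " region of interest",
           call. = FALSE)
    }
  }
  .with_seed(seed, .synthesize_impl(stages, sfreq, channels, noise_uv,
                                    subject_id, cfg))
}

.synthesize_impl <- function(stages, sfreq, channels, noise_uv,
                             subject_id, cfg) {
  n_eeg <- length(channels)
  n_sec <- length(stages)
  n <- n_sec * sfreq
  eeg <- matrix(0, n_eeg, n)
  heog <- matrix(0, 2, n)   # HEOGL, HEOGR
  fc_idx <- which(channels %in% cfg$frontocentral)
  roi_gain <- function(region) {
    g <- rep(1, n_eeg)
    g[channels %in% cfg$roi[[region]]] <- 2
    g
  }
  runs <- rle(stages)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  grapho_toggle <- TRUE
  for (ri in seq_along(runs$values)) {
    st <- runs$values[ri]
    sec0 <- starts[ri] - 1L
    len_s <- runs$lengths[ri]
    idx <- (sec0 * sfreq + 1L):(ends[ri] * sfreq)
    nr <- length(idx)
    tt <- (seq_len(nr) - 1) / sfreq
    block <- .pink_noise(n_eeg, nr, rms = 2)
    if (st %in% c("A1", "A2", "A3")) {
      region <- c(A1 = "occipital", A2 = "parietal", A3 = "frontal")[st]
      gain <- roi_gain(region)
      phase <- stats::runif(n_eeg, 0, 2 * pi)
      amp <- 20  # uV peak at gain 1
      for (i in seq_len(n_eeg)) {
        block[i, ] <- block[i, ] +
          gain[i] * amp * sin(2 * pi * 10 * tt + phase[i])
      }
    } else if (st %in% c("0", "B1")) {
      block <- block + .band_noise(n_eeg, nr, sfreq, c(12, 25), rms = 6)
      if (st == "B1") {
        sem <- 30 * sin(2 * pi * 0.25 * tt + stats::runif(1, 0, 2 * pi))
        heog[1, idx] <- heog[1, idx] + sem
        heog[2, idx] <- heog[2, idx] - sem
      }
    } else if (st == "B2/3") {
      block <- block + .band_noise(n_eeg, nr, sfreq, c(2, 6), rms = 15)
    } else if (st == "C") {
      block <- block + .band_noise(n_eeg, nr, sfreq, c(2, 6), rms = 10)
      for (s in seq_len(len_s)) {
        off <- (s - 1L) * sfreq
        if (grapho_toggle) {
          burst_n <- round(0.8 * sfreq)
          bt <- (seq_len(burst_n) - 1) / sfreq
          # short cosine ramps, flat middle: the envelope must clear the
          # detector's amplitude floor for most of the burst
          ramp_n <- round(0.1 * sfreq)
          env <- rep(1, burst_n)
          env[seq_len(ramp_n)] <- 0.5 - 0.5 * cos(pi * seq_len(ramp_n) /
                                                    ramp_n)
          env[burst_n + 1 - seq_len(ramp_n)] <- env[seq_len(ramp_n)]
          burst <- 40 * env * sin(2 * pi * 13 * bt)
          lo <- off + round(0.1 * sfreq)
          block[fc_idx, (lo + 1):(lo + burst_n)] <-
            block[fc_idx, (lo + 1):(lo + burst_n)] +
            rep(burst, each = length(fc_idx))
        } else {
          kn <- sfreq  # 1-s biphasic wave
          kt <- (seq_len(kn) - 1) / sfreq
          kc <- 80 * sin(2 * pi * 1 * kt)
          block[fc_idx, (off + 1):(off + kn)] <-
            block[fc_idx, (off + 1):(off + kn)] +
            rep(kc, each = length(fc_idx))
        }
        grapho_toggle <- !grapho_toggle
      }
    }
    eeg[, idx] <- block
  }
  eeg <- eeg + matrix(stats::rnorm(n_eeg * n, sd = noise_uv), n_eeg, n)
  eog <- rbind(heog, matrix(0, 2, n)) +
    matrix(stats::rnorm(4 * n, sd = noise_uv), 4, n)
  data <- rbind(eeg, eog)
  labels <- c(channels, .SYNTH_EOG)
  recording(subject_id, sfreq, data, labels)
}

# ---------------------------------------------------------------------------
# cohort generation

#' Default cohort configuration
#'
#' Group sizes and per-variable means/SDs emulating the descriptive
#' statistics of the study cohort: 78 non-hypoaroused and 24 hypoaroused
#' fatigued patients. Scale-total distributions are truncated normal,
#' rounded and clipped to the instrument's range.
#'
#' @param n_non_hypo,n_hypo Group sizes (defaults 78 and 24).
#' @param seed Integer seed.
#' @return List of class `cohort_config` with a `vars` table of
#'   per-group mean/SD for every generated variable.
#' @export
cohort_config <- function(n_non_hypo = 78, n_hypo = 24, seed = 1) {
  if (n_non_hypo < 2 || n_hypo < 2) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  vars <- data.frame(
    var = c("mfi_general", "mfi_mental", "mfi_physical", "mfi_activity",
            "mfi_motivation", "bdi_total", "ess_total", "sss",
            "sfar_quality", "time_in_bed", "age", "stability_score"),
    lo  = c(4, 4, 4, 4, 4, 0, 0, 1, 1, 3, 18, 7),
    hi  = c(20, 20, 20, 20, 20, 63, 24, 7, 5, 12, 75, 11),
    mean_non_hypo = c(14.9, 14.4, 13.7, 15.3, 13.5, 29.2, 8.3, 3.4,
                      2.7, 7.15, 38.4, 8.9),
    sd_non_hypo   = c(2.4, 3.3, 3.3, 2.8, 3.1, 8.8, 4.0, 1.2,
                      1.03, 1.73, 12.2, 1.6),
    mean_hypo = c(15.4, 15.9, 14.8, 16.2, 13.7, 30.3, 10.4, 4.1,
                  2.6, 7.4, 35.3, 4.5),
    sd_hypo   = c(2.5, 2.3, 2.7, 3.1, 3.5, 7.9, 4.0, 1.2,
                  0.7, 1.32, 13.5, 1.3),
    digits = c(0, 0, 0, 0, 0, 0, 0, 0, 1, 2, 0, 0))
  vars$hi[vars$var == "stability_score"] <- 11
  structure(list(n_non_hypo = n_non_hypo, n_hypo = n_hypo, seed = seed,
                 vars = vars,
                 sex_f_prop = c(non_hypo = 45 / 78, hypo = 16 / 24)),
            class = "cohort_config")
}

# truncated-normal draw, rounded and clipped to [lo, hi]
.rtruncnorm_round <- function(n, mean, sd, lo, hi, digits = 0) {
  if (mean < lo || mean > hi) {
    stop("infeasible mean ", mean, " outside scale range [", lo, ",", hi,
         "]", call. = FALSE)
  }
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  round(out, digits)
}

# uniformly allocate `total` over n_items items each in [lo, hi]
.distribute_total <- function(total, n_items, lo, hi) {
  add <- total - n_items * lo
  if (add < 0 || add > n_items * (hi - lo)) {
    stop("total ", total, " infeasible for ", n_items, " items in [",
         lo, ",", hi, "]", call. = FALSE)
  }
  slots <- rep(seq_len(n_items), each = hi - lo)
  counts <- tabulate(sample(slots, add), nbins = n_items)
  lo + counts
}

.fmt_clock <- function(hours) {
  hours <- hours %% 24
  h <- floor(hours)
  m <- round((hours - h) * 60)
  h <- (h + m %/% 60) %% 24; m <- m %% 60
  sprintf("%02d:%02d", h, m)
}

#' Generate a synthetic cohort questionnaire table
#'
#' Draws per-subject scale totals from the group's configured truncated
#' normal, then back-fills item-level responses consistent with each
#' total (uniform allocation across items; MFI reversed items recoded to
#' their raw polarity). Age and sex follow the study's margins.
#' Deterministic given the config seed.
#'
#' @param cfg A [cohort_config()].
#' @return Data frame in the cohort-CSV layout of [read_cohort()], with
#'   `group` and a generator-side `stability_score` column.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  .with_seed(cfg$seed, .generate_cohort_impl(cfg))
}

.generate_cohort_impl <- function(cfg) {
  key <- mfi_key()
  groups <- c(rep("non_hypoaroused", cfg$n_non_hypo),
              rep("hypoaroused", cfg$n_hypo))
  n <- length(groups)
  v <- function(name, grp) {
    row <- cfg$vars[cfg$vars$var == name, ]
    hyp <- grp == "hypoaroused"
    mean <- ifelse(hyp, row$mean_hypo, row$mean_non_hypo)
    sd <- ifelse(hyp, row$sd_hypo, row$sd_non_hypo)
    .rtruncnorm_round(length(grp), mean[1], sd[1], row$lo, row$hi,
                      row$digits)
  }
  draw_by_group <- function(name) {
    out <- numeric(n)
    for (g in unique(groups)) {
      sel <- groups == g
      out[sel] <- v(name, groups[sel])
    }
    out
  }
  mfi_dims <- list(general_fatigue = draw_by_group("mfi_general"),
                   physical_fatigue = draw_by_group("mfi_physical"),
                   reduced_activity = draw_by_group("mfi_activity"),
                   reduced_motivation = draw_by_group("mfi_motivation"),
                   mental_fatigue = draw_by_group("mfi_mental"))
  bdi_total <- draw_by_group("bdi_total")
  ess_total <- draw_by_group("ess_total")
  sss <- draw_by_group("sss")
  quality <- draw_by_group("sfar_quality")
  tib <- draw_by_group("time_in_bed")
  age <- draw_by_group("age")
  stab <- numeric(n)
  stab_rows <- cfg$vars[cfg$vars$var == "stability_score", ]
  sel_nh <- groups == "non_hypoaroused"
  stab[sel_nh] <- .rtruncnorm_round(sum(sel_nh), stab_rows$mean_non_hypo,
                                    stab_rows$sd_non_hypo, 7, 11)
  stab[!sel_nh] <- .rtruncnorm_round(sum(!sel_nh), stab_rows$mean_hypo,
                                     stab_rows$sd_hypo, 1, 6)
  sex <- character(n)
  for (g in unique(groups)) {
    sel <- groups == g
    p <- cfg$sex_f_prop[[if (g == "hypoaroused") "hypo" else "non_hypo"]]
    sex[sel] <- ifelse(stats::runif(sum(sel)) < p, "F", "M")
  }

  mfi_items <- matrix(NA_real_, n, 20,
                      dimnames = list(NULL, sprintf("mfi_%02d", 1:20)))
  for (i in seq_len(n)) {
    for (dn in names(key$dimensions)) {
      idx <- key$dimensions[[dn]]
      vals <- .distribute_total(mfi_dims[[dn]][i], 4, 1, 5)
      rev <- idx %in% key$reversed
      vals[rev] <- 6 - vals[rev]
      mfi_items[i, idx] <- vals
    }
  }
  bdi_items <- t(vapply(bdi_total, .distribute_total, numeric(21),
                        n_items = 21, lo = 0, hi = 3))
  colnames(bdi_items) <- sprintf("bdi_%02d", 1:21)
  ess_items <- t(vapply(ess_total, .distribute_total, numeric(8),
                        n_items = 8, lo = 0, hi = 3))
  colnames(ess_items) <- sprintf("ess_%02d", 1:8)
  q_items <- t(vapply(round(quality * 5), .distribute_total, numeric(5),
                      n_items = 5, lo = 1, hi = 5))
  colnames(q_items) <- sprintf("sfa_q%d", 1:5)
  bed <- (23 + stats::rnorm(n, 0.25, 0.75)) %% 24
  rise <- (bed + tib) %% 24

  data.frame(subject_id = sprintf("S%03d", seq_len(n)),
             age = age, sex = sex, group = groups,
             stability_score = stab,
             med_status = ifelse(stats::runif(n) < 0.43, "medicated",
                                 "unmedicated"),
             mfi_items, bdi_items, ess_items,
             sss = sss, q_items,
             sfa_bedtime = .fmt_clock(bed),
             sfa_risetime = .fmt_clock(rise),
             stringsAsFactors = FALSE)
}
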