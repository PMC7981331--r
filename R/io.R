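#' @name eeg_io
#' @title EEG and tabular input/output
#' @description
#' Readers and writers for the two EEG interchange formats used by the
#' pipeline (BrainVision .vhdr/.vmrk/.eeg triplets and EDF), the
#' per-second stage-sequence CSV, and the cohort questionnaire CSV.
#' All readers validate channel/row counts and never silently drop data.
NULL

# extended 10-20 labels accepted for EEG channels
.TEN_TWENTY <- c(
  "Fp1", "Fp2", "Fpz", "AF3", "AF4", "AF7", "AF8", "AFz",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT7", "FT8", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
  "T7", "T8", "T3", "T4", "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
  "TP7", "TP8", "TP9", "TP10", "CP5", "CP3", "CP1", "CPz", "CP2",
  "CP4", "CP6", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO3", "PO4", "PO7", "PO8", "PO9", "PO10", "POz", "O1", "Oz", "O2",
  "T5", "T6", "Iz")

#' Infer channel roles from labels
#'
#' Default map: labels matching `eog_pattern` are EOG channels —
#' horizontal when they also match `horizontal_pattern`, vertical
#' otherwise; everything else must carry a recognised extended 10-20
#' label and becomes EEG.
#'
#' @param labels Character vector of channel labels.
#' @param eog_pattern Regex marking EOG channels (default "EOG",
#'   case-insensitive).
#' @param horizontal_pattern Regex marking horizontal EOG among the EOG
#'   channels (default "^H|L$|R$": leading H or trailing L/R, the canthus
#'   electrodes).
#' @return Character vector of roles: "EEG", "EOG-horizontal",
#'   "EOG-vertical".
#' @export
infer_channel_roles <- function(labels, eog_pattern = "EOG",
                                horizontal_pattern = "^H|L$|R$") {
  is_eog <- grepl(eog_pattern, labels, ignore.case = TRUE)
  roles <- ifelse(is_eog,
                  ifelse(grepl(horizontal_pattern, labels, ignore.case = TRUE),
                         "EOG-horizontal", "EOG-vertical"),
                  "EEG")
  bad <- roles == "EEG" & !labels %in% .TEN_TWENTY
  if (any(bad)) {
    stop("unrecognised EEG channel label(s): ",
         paste(labels[bad], collapse = ", "),
         "; EEG channels must use extended 10-20 names", call. = FALSE)
  }
  roles
}

#' Construct an EEG recording object
#'
#' @param subject_id Subject identifier.
#' @param sfreq Sampling rate in Hz (> 0).
#' @param data Channels x samples numeric matrix in microvolts.
#' @param channel_labels Character vector, one per data row.
#' @param channel_roles Optional roles; inferred from labels when NULL.
#' @param start_time Optional POSIXct wall-clock start.
#' @return Object of class `eeg_recording`.
#' @export
recording <- function(subject_id, sfreq, data, channel_labels,
                      channel_roles = NULL, start_time = NULL) {
  data <- as.matrix(data)
  if (nrow(data) != length(channel_labels)) {
    stop("data row count (", nrow(data), ") must equal number of channel ",
         "labels (", length(channel_labels), ")", call. = FALSE)
  }
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0) {
    stop("sfreq must be a positive number", call. = FALSE)
  }
  if (is.null(channel_roles)) channel_roles <- infer_channel_roles(channel_labels)
  rownames(data) <- channel_labels
  structure(
    list(subject_id = as.character(subject_id), sfreq = sfreq, data = data,
         channel_labels = as.character(channel_labels),
         channel_roles = channel_roles, start_time = start_time),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels (%d EEG), %.1f s @ %g Hz\n",
              x$subject_id, nrow(x$data), sum(x$channel_roles == "EEG"),
              ncol(x$data) / x$sfreq, x$sfreq))
  invisible(x)
}

.eeg_channels <- function(rec) which(rec$channel_roles == "EEG")

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Numeric seconds.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$sfreq

# ---------------------------------------------------------------------------
# BrainVision triplet

.parse_ini <- function(lines) {
  sec <- ""
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && nzchar(sec)) {
      kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
      out[[sec]][[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Parses the .vhdr text header, checks the .vmrk marker file and binary
#' data file exist, and reads the signal in microvolts. Supported binary
#' encodings: IEEE_FLOAT_32 and INT_16 (scaled by the per-channel
#' resolution); orientations MULTIPLEXED and VECTORIZED.
#'
#' @param path Path to the .vhdr header file.
#' @param subject_id Optional subject id (default: header file stem).
#' @param role_map Function mapping labels to roles, default
#'   [infer_channel_roles()].
#' @return An [recording()] object.
#' @export
read_brainvision <- function(path, subject_id = NULL,
                             role_map = infer_channel_roles) {
  if (!file.exists(path)) stop("header file not found: ", path, call. = FALSE)
  hdr <- .parse_ini(readLines(path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stop("BrainVision format error: no [Common Infos] in ",
                        path, call. = FALSE)
  dir <- dirname(path)
  data_file <- file.path(dir, ci$DataFile)
  marker_file <- file.path(dir, ci$MarkerFile)
  if (is.null(ci$DataFile) || !file.exists(data_file)) {
    stop("BrainVision format error: missing data file ",
         ci$DataFile %||% "<unset>", call. = FALSE)
  }
  if (is.null(ci$MarkerFile) || !file.exists(marker_file)) {
    stop("BrainVision format error: missing marker file ",
         ci$MarkerFile %||% "<unset>", call. = FALSE)
  }
  n_chan <- as.integer(ci$NumberOfChannels)
  sfreq <- 1e6 / as.numeric(ci$SamplingInterval)  # interval is in µs
  fmt <- hdr[["Binary Infos"]]$BinaryFormat
  orient <- toupper(ci$DataOrientation %||% "MULTIPLEXED")
  chinfo <- hdr[["Channel Infos"]]
  if (length(chinfo) != n_chan) {
    stop("BrainVision format error: ", length(chinfo),
         " channel entries but NumberOfChannels=", n_chan, call. = FALSE)
  }
  ord <- order(as.integer(sub("^Ch", "", names(chinfo))))
  parts <- lapply(chinfo[ord], function(v) strsplit(v, ",")[[1]])
  labels <- vapply(parts, `[`, "", 1)
  resol <- vapply(parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, 0)

  sz <- file.info(data_file)$size
  if (identical(fmt, "IEEE_FLOAT_32")) {
    raw_vals <- readBin(data_file, "numeric", n = sz / 4, size = 4,
                        endian = "little")
  } else if (identical(fmt, "INT_16")) {
    raw_vals <- readBin(data_file, "integer", n = sz / 2, size = 2,
                        signed = TRUE, endian = "little")
  } else {
    stop("unsupported BrainVision binary dialect: ", fmt %||% "<unset>",
         call. = FALSE)
  }
  n_samp <- length(raw_vals) %/% n_chan
  raw_vals <- raw_vals[seq_len(n_samp * n_chan)]
  data <- if (orient == "MULTIPLEXED") {
    matrix(raw_vals, nrow = n_chan)
  } else if (orient == "VECTORIZED") {
    t(matrix(raw_vals, ncol = n_chan))
  } else {
    stop("unsupported BrainVision orientation: ", orient, call. = FALSE)
  }
  data <- data * resol
  if (is.null(subject_id)) subject_id <- sub("\\.vhdr$", "", basename(path))
  recording(subject_id, sfreq, data, labels, role_map(labels))
}

#' Write a BrainVision triplet
#'
#' Writes .vhdr, .vmrk and an IEEE_FLOAT_32 multiplexed binary data file.
#'
#' @param rec An `eeg_recording`.
#' @param path Path for the .vhdr file; companions are named alongside.
#' @return Invisibly, the header path.
#' @export
write_brainvision <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  stem <- sub("\\.vhdr$", "", basename(path))
  dir <- dirname(path)
  eeg_name <- paste0(stem, ".eeg"); vmrk_name <- paste0(stem, ".vmrk")
  n_chan <- nrow(rec$data)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", eeg_name),
    paste0("MarkerFile=", vmrk_name),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_chan),
    paste0("SamplingInterval=", format(1e6 / rec$sfreq, digits = 15)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_chan), rec$channel_labels))
  writeLines(hdr, file.path(dir, paste0(stem, ".vhdr")))
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", eeg_name),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000"),
    file.path(dir, vmrk_name))
  con <- file(file.path(dir, eeg_name), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  invisible(file.path(dir, paste0(stem, ".vhdr")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# EDF

.edf_pad <- function(x, width) {
  s <- formatC(as.character(x), width = width, flag = "-")
  substr(s, 1L, width)  # hard-truncate: EDF fields are fixed width
}

# render a number into an 8-char EDF ASCII field without losing the
# magnitude to truncation
.edf_num <- function(x) {
  vapply(x, function(v) {
    for (s in c(formatC(v, format = "g", digits = 7),
                formatC(v, format = "f", digits = 2),
                formatC(round(v)))) {
      if (nchar(s) <= 8L) return(s)
    }
    stop("numeric value does not fit an EDF header field: ", v,
         call. = FALSE)
  }, "")
}

#' Write a recording to EDF
#'
#' One data record per second; 16-bit integers scaled per channel to the
#' channel's physical range (so round-trips are exact to the 16-bit
#' quantisation step). The sampling rate must be a whole number of
#' samples per second and the duration a whole number of seconds.
#'
#' @param rec An `eeg_recording`.
#' @param path Output .edf path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  nr_per_rec <- rec$sfreq
  if (nr_per_rec != round(nr_per_rec)) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  n_rec <- floor(ncol(rec$data) / nr_per_rec)
  if (n_rec < 1) stop("recording shorter than one EDF record", call. = FALSE)
  used <- seq_len(n_rec * nr_per_rec)
  pmin <- apply(rec$data[, used, drop = FALSE], 1, min)
  pmax <- apply(rec$data[, used, drop = FALSE], 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) {
    s <- paste(.edf_pad(x, w), collapse = "")
    writeChar(s, con, nchars = nchar(s), eos = NULL)
  }
  wr("0", 8)                               # version
  wr(rec$subject_id, 80)                   # patient id
  wr("arousalstrat synthetic", 80)         # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)     # start date/time
  wr(256 * (ns + 1), 8)                    # header bytes
  wr("", 44)                               # reserved
  wr(n_rec, 8)                             # number of records
  wr("1", 8)                               # record duration (s)
  wr(ns, 4)                                # number of signals
  wr(rec$channel_labels, 16)
  wr(rep("", ns), 80)                      # transducer
  wr(rep("uV", ns), 8)                     # physical dimension
  wr(.edf_num(pmin), 8)
  wr(.edf_num(pmax), 8)
  wr(rep(dmin, ns), 8)
  wr(rep(dmax, ns), 8)
  wr(rep("", ns), 80)                      # prefiltering
  wr(rep(nr_per_rec, ns), 8)
  wr(rep("", ns), 32)                      # reserved
  # re-read the header's physical bounds so the scaling we apply matches
  # what a reader will parse back from the 8-char ASCII fields
  pmin_r <- as.numeric(.edf_num(pmin))
  pmax_r <- as.numeric(.edf_num(pmax))
  scale <- (dmax - dmin) / (pmax_r - pmin_r)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * nr_per_rec + 1):(r * nr_per_rec)
    block <- rec$data[, idx, drop = FALSE]
    dig <- round((block - pmin_r) * scale + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF/EDF+ recording
#'
#' @param path .edf file path.
#' @param subject_id Optional override; default is the EDF patient field.
#' @param role_map Function mapping labels to roles.
#' @return An [recording()] object in microvolts.
#' @export
read_edf <- function(path, subject_id = NULL,
                     role_map = infer_channel_roles) {
  if (!file.exists(path)) stop("EDF file not found: ", path, call. = FALSE)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) {
    stop("EDF format error: file too short for a header (", sz, " bytes)",
         call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  patient <- rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(hdr_bytes, n_rec, rec_dur, ns)) || ns < 1 || rec_dur <= 0) {
    stop("EDF format error: corrupt header in ", path, call. = FALSE)
  }
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  nr <- as.integer(rdv(8))
  rdv(32)
  if (anyNA(c(pmin, pmax, dmin, dmax, nr))) {
    stop("EDF format error: corrupt signal headers in ", path, call. = FALSE)
  }
  if (length(unique(nr / rec_dur)) != 1L) {
    stop("EDF with per-signal sampling rates is not supported", call. = FALSE)
  }
  sfreq <- nr[1] / rec_dur
  data <- matrix(NA_real_, nrow = ns, ncol = n_rec * nr[1])
  offs <- c(0L, cumsum(nr))
  for (r in seq_len(n_rec)) {
    vals <- readBin(con, "integer", n = sum(nr), size = 2, signed = TRUE,
                    endian = "little")
    if (length(vals) < sum(nr)) {
      stop("EDF format error: truncated data record ", r, call. = FALSE)
    }
    for (s in seq_len(ns)) {
      dig <- vals[(offs[s] + 1):offs[s + 1]]
      phys <- (dig - dmin[s]) * (pmax[s] - pmin[s]) / (dmax[s] - dmin[s]) +
        pmin[s]
      data[s, ((r - 1) * nr[1] + 1):(r * nr[1])] <- phys
    }
  }
  if (is.null(subject_id)) {
    subject_id <- if (nzchar(patient)) patient else
      sub("\\.edf$", "", basename(path), ignore.case = TRUE)
  }
  recording(subject_id, sfreq, data, labels, role_map(labels))
}

# ---------------------------------------------------------------------------
# stage-sequence CSV

#' Write a stage sequence to CSV
#'
#' Columns: segment_index (0-based, half-open 1-s windows), stage,
#' artifact (0/1).
#'
#' @param record A [stage_sequence()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_stage_sequence <- function(record, path) {
  stopifnot(inherits(record, "stage_sequence"))
  df <- data.frame(segment_index = seq_along(record$stages) - 1L,
                   stage = record$stages,
                   artifact = as.integer(record$artifact_mask))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a stage sequence from CSV
#'
#' @param path CSV written by [write_stage_sequence()].
#' @param subject_id Subject id to attach (default: file stem).
#' @return A [stage_sequence()].
#' @export
read_stage_sequence <- function(path, subject_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(stage = "character"))
  need <- c("segment_index", "stage", "artifact")
  if (!all(need %in% names(df))) {
    stop("stage CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- !df$stage %in% VIGILANCE_STAGES
  if (any(bad)) {
    stop("parse error in ", path, " line ", which(bad)[1] + 1L,
         ": unknown stage token \"", df$stage[which(bad)[1]], "\"",
         call. = FALSE)
  }
  if (!identical(df$segment_index, seq_len(nrow(df)) - 1L) &&
      !identical(as.integer(df$segment_index), seq_len(nrow(df)) - 1L)) {
    stop("segment_index must be contiguous 0-based", call. = FALSE)
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.csv$", "", basename(path))
  }
  stage_sequence(subject_id, df$stage, df$artifact == 1L)
}

# ---------------------------------------------------------------------------
# cohort CSV

#' Read a cohort questionnaire table
#'
#' One row per subject with item-level questionnaire columns
#' (mfi_01..mfi_20, bdi_01..bdi_21, ess_01..ess_08, sss,
#' sfa_q1..sfa_q5, sfa_bedtime, sfa_risetime), demographics (age, sex)
#' and med_status. Missing items are explicit NA (empty cells).
#'
#' @param path CSV path.
#' @return Data frame with one row per subject.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!"subject_id" %in% names(df)) {
    stop("cohort CSV must have a subject_id column", call. = FALSE)
  }
  dup <- duplicated(df$subject_id)
  if (any(dup)) {
    stop("duplicate subject_id in cohort table: ",
         paste(unique(df$subject_id[dup]), collapse = ", "), call. = FALSE)
  }
  for (col in grep("^bdi_(16|18)$", names(df), value = TRUE)) {
    df[[col]] <- as.character(df[[col]])
  }
  df
}

#' Write a cohort questionnaire table
#' @param cohort Data frame from [generate_cohort()] or [read_cohort()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
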