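#' @name questionnaires
#' @title Clinical questionnaire scoring
#' @description
#' Scoring of the five self-report instruments used around the resting-EEG
#' recording: MFI-20 (five fatigue dimensions, each 4-20), BDI-II
#' (depression severity, 0-63), ESS (trait daytime sleepiness, 0-24),
#' SSS (state sleepiness, single 1-7 rating) and the SF-A/R sleep
#' inventory (sleep quality 1-5 and total time in bed). A questionnaire
#' with more than 2 missing items is not scored; with 1-2 missing items
#' the missing values are imputed by the rounded person mean within the
#' scale (for the MFI, within the item's dimension).
NULL

#' MFI-20 scoring key
#'
#' Item-to-dimension assignment and reversal set of the standard
#' 20-item Multidimensional Fatigue Inventory. Items are answered 1-5;
#' reversed items are recoded 6 - value before summing, so each 4-item
#' dimension scores 4-20 with higher = more fatigue.
#'
#' @return List with `dimensions` (named list of item indices) and
#'   `reversed` (integer vector of reversed item numbers).
#' @export
mfi_key <- function() {
  list(
    dimensions = list(
      general_fatigue    = c(1L, 5L, 12L, 16L),
      physical_fatigue   = c(2L, 8L, 14L, 20L),
      reduced_activity   = c(3L, 6L, 10L, 17L),
      reduced_motivation = c(4L, 9L, 15L, 18L),
      mental_fatigue     = c(7L, 11L, 13L, 19L)),
    reversed = c(2L, 5L, 9L, 10L, 13L, 14L, 16L, 17L, 18L, 19L))
}

.check_items <- function(items, n, lo, hi, what) {
  if (length(items) != n) {
    stop(what, " expects ", n, " items, got ", length(items), call. = FALSE)
  }
  ok <- is.na(items) | (items >= lo & items <= hi & items == round(items))
  if (!all(ok)) {
    stop(what, " item values out of range [", lo, ",", hi, "] at position(s) ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  }
  as.numeric(items)
}

.too_many_missing <- function(items, max_missing = 2L) {
  sum(is.na(items)) > max_missing
}

#' Score the MFI-20
#'
#' Reversed items are recoded (6 - value); each dimension is the sum of
#' its four items; a missing item is imputed by the rounded mean of the
#' same dimension's answered items. More than 2 missing items overall
#' yields an exclusion result instead of scores.
#'
#' @param items Numeric vector of 20 raw item values (1-5), `NA` for
#'   missing.
#' @param key Scoring key, see [mfi_key()].
#' @return List with `valid`; if valid, `scores` (named vector of the
#'   five dimension scores, each 4-20) and `low_confidence` (TRUE when a
#'   dimension had to impute from fewer than 3 answered items); otherwise
#'   `reason`.
#' @export
score_mfi <- function(items, key = mfi_key()) {
  items <- .check_items(items, 20L, 1, 5, "MFI-20")
  if (.too_many_missing(items)) {
    return(list(valid = FALSE, reason = "mfi_missing_items"))
  }
  recoded <- items
  recoded[key$reversed] <- 6 - recoded[key$reversed]
  low_conf <- FALSE
  scores <- vapply(key$dimensions, function(idx) {
    v <- recoded[idx]
    if (anyNA(v)) {
      answered <- v[!is.na(v)]
      if (length(answered) < 3L) low_conf <<- TRUE
      v[is.na(v)] <- round(mean(answered))
    }
    sum(v)
  }, numeric(1))
  list(valid = TRUE, scores = scores, low_confidence = low_conf)
}

#' Map a BDI-II item response to its numeric score
#'
#' Items 16 (sleep pattern) and 18 (appetite) offer seven graded options
#' 0, 1a, 1b, 2a, 2b, 3a, 3b which collapse to 0, 1, 1, 2, 2, 3, 3.
#'
#' @param x Character or numeric vector of raw responses.
#' @return Numeric scores 0-3 (`NA` preserved).
#' @export
bdi_item_value <- function(x) {
  map <- c("0" = 0, "1" = 1, "1a" = 1, "1b" = 1, "2" = 2, "2a" = 2,
           "2b" = 2, "3" = 3, "3a" = 3, "3b" = 3)
  x <- trimws(tolower(as.character(x)))
  out <- unname(map[x])
  out[is.na(x) | x == ""] <- NA
  if (any(is.na(out) & !(is.na(x) | x == ""))) {
    stop("unrecognised BDI-II response token(s): ",
         paste(unique(x[is.na(out) & !is.na(x)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Score the BDI-II
#'
#' Sum of 21 items scored 0-3 (total 0-63); missing items (at most 2)
#' imputed by the rounded person mean of answered items.
#'
#' @param items Vector of 21 raw responses; items 16 and 18 may use the
#'   graded tokens "1a".."3b".
#' @return List with `valid` and, if valid, `total` (0-63); otherwise
#'   `reason`.
#' @export
score_bdi <- function(items) {
  if (length(items) != 21L) {
    stop("BDI-II expects 21 items, got ", length(items), call. = FALSE)
  }
  vals <- bdi_item_value(items)
  .check_items(vals, 21L, 0, 3, "BDI-II")
  if (.too_many_missing(vals)) {
    return(list(valid = FALSE, reason = "bdi_missing_items"))
  }
  if (anyNA(vals)) vals[is.na(vals)] <- round(mean(vals, na.rm = TRUE))
  list(valid = TRUE, total = sum(vals))
}

#' Score the Epworth Sleepiness Scale
#'
#' Sum of 8 items rated 0-3 (total 0-24); totals strictly greater than 10
#' flag mild excessive daytime sleepiness.
#'
#' @param items Numeric vector of 8 item values (0-3).
#' @return List with `valid` and, if valid, `total` and `sleepy_flag`;
#'   otherwise `reason`.
#' @export
score_ess <- function(items) {
  items <- .check_items(items, 8L, 0, 3, "ESS")
  if (.too_many_missing(items)) {
    return(list(valid = FALSE, reason = "ess_missing_items"))
  }
  if (anyNA(items)) items[is.na(items)] <- round(mean(items, na.rm = TRUE))
  total <- sum(items)
  list(valid = TRUE, total = total, sleepy_flag = total > 10)
}

#' Parse a clock time "HH:MM" to fractional hours
#' @param x Character vector of clock times.
#' @return Numeric hours in [0, 24).
#' @export
parse_clock <- function(x) {
  out <- rep(NA_real_, length(x))
  nz <- !is.na(x) & nzchar(x)
  m <- regmatches(x[nz], regexec("^([0-9]{1,2}):([0-9]{2})$", x[nz]))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) {
    stop("unparsable clock time(s): ", paste(x[nz][bad], collapse = ", "),
         call. = FALSE)
  }
  h <- vapply(m, function(g) as.numeric(g[2]), 0)
  mi <- vapply(m, function(g) as.numeric(g[3]), 0)
  if (any(h > 23 | mi > 59)) stop("clock time out of range", call. = FALSE)
  out[nz] <- h + mi / 60
  out
}

#' Score SF-A/R sleep quality and total time in bed
#'
#' Sleep quality is the mean of the 5-point quality items (1 impaired to
#' 5 excellent). Total time in bed is rise time minus bedtime with
#' midnight wrap-around, in hours.
#'
#' @param quality_items Numeric vector of quality item values (1-5).
#' @param bed_time,rise_time Clock times "HH:MM".
#' @return List with `quality` and `time_in_bed_hours` (either may be
#'   `NA` when its inputs are missing).
#' @export
score_sfar <- function(quality_items, bed_time = NA, rise_time = NA) {
  quality_items <- .check_items(quality_items, length(quality_items), 1, 5,
                                "SF-A/R quality")
  quality <- if (all(is.na(quality_items))) NA_real_ else
    mean(quality_items, na.rm = TRUE)
  tib <- NA_real_
  b <- parse_clock(bed_time)
  r <- parse_clock(rise_time)
  if (!is.na(b) && !is.na(r)) {
    tib <- (r - b) %% 24
    if (tib <= 0) {
      stop("impossible bed/rise times: zero or negative time in bed",
           call. = FALSE)
    }
  }
  list(quality = quality, time_in_bed_hours = tib)
}

#' Read an MFI norm table
#'
#' Expects a CSV with columns sex, age_lo, age_hi, dimension, p75 giving
#' the 75th-percentile threshold per sex and age band for each MFI
#' dimension. The table shipped in `inst/extdata/mfi_norms_synthetic.csv`
#' is a synthetic placeholder: real population norms must be supplied for
#' substantive use.
#'
#' @param path CSV path; default is the shipped synthetic placeholder.
#' @return Data frame of norm thresholds.
#' @export
read_mfi_norms <- function(path = system.file("extdata",
                                              "mfi_norms_synthetic.csv",
                                              package = "arousalstrat")) {
  norms <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_lo", "age_hi", "dimension", "p75")
  if (!all(need %in% names(norms))) {
    stop("norm table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(norms$p75 < 4 | norms$p75 > 20)) {
    stop("norm thresholds must lie in [4, 20]", call. = FALSE)
  }
  norms
}

#' Apply the fatigue inclusion rule
#'
#' A subject is included when the general-fatigue dimension score
#' strictly exceeds the 75th-percentile norm threshold for the subject's
#' sex and age band.
#'
#' @param general_fatigue General-fatigue dimension score (4-20).
#' @param norms Norm table from [read_mfi_norms()].
#' @param age Age in years.
#' @param sex "F" or "M".
#' @return Logical: include the subject?
#' @export
apply_inclusion <- function(general_fatigue, norms, age, sex) {
  hit <- norms$dimension == "general_fatigue" & norms$sex == sex &
    norms$age_lo <= age & age <= norms$age_hi
  if (sum(hit) != 1L) {
    stop("no (or ambiguous) norm cell for sex=", sex, " age=", age,
         call. = FALSE)
  }
  general_fatigue > norms$p75[hit]
}
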