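#' Arousal stability score
#'
#' Summarises a 15-min resting-EEG vigilance stage sequence into an
#' integer score 1..11 describing how far and how early arousal declined.
#' The recording is divided into three 5-min blocks by original segment
#' timing (segments 1-300, 301-600, 601-900 for a full recording; shorter
#' recordings use the blocks they reach). Criteria are evaluated in
#' ascending score order, first match wins:
#'
#' \itemize{
#'   \item 1, 2, 3 — at least one C stage occurred; the earliest
#'     C-containing block fixes the score (minutes 1-5 -> 1, 6-10 -> 2,
#'     11-15 -> 3).
#'   \item 4, 5, 6 — at least 1/3 of a block's segments are B2/3;
#'     earliest qualifying block (1-5 -> 4, 6-10 -> 5, 11-15 -> 6).
#'   \item 7, 8, 9 — at least 1/3 of a block's segments are B1; earliest
#'     qualifying block (1-5 -> 7, 6-10 -> 8, 11-15 -> 9).
#'   \item 11 — at least 2/3 of all segments are 0 or A1.
#'   \item 10 — at least 2/3 of all segments are 0, A1, A2 or A3.
#' }
#'
#' If no criterion fires (possible with scattered sub-threshold B stages)
#' the configurable fallback score is returned and flagged. Artifact
#' segments are excluded from numerators and denominators but keep their
#' position for block assignment; fraction comparisons use exact integer
#' arithmetic.
#'
#' @param seq A [stage_sequence()], or a character vector of stage names.
#' @param block_len_s Block length in seconds (default 300 = 5 min).
#' @param fallback_score Score returned when no criterion fires
#'   (default 10).
#' @return An object of class `stability_result` with fields `score`,
#'   `matched_criterion`, `group` ("hypoaroused" if score <= 6 else
#'   "non_hypoaroused"), `block_fractions` (per-block B1 and B2/3
#'   fractions among non-artifact segments) and `c_first_block`.
#' @export
stability_score <- function(seq, block_len_s = 300L, fallback_score = 10L) {
  if (is.character(seq)) seq <- stage_sequence("anon", seq)
  stopifnot(inherits(seq, "stage_sequence"))
  n <- length(seq$stages)
  keep <- !seq$artifact_mask
  if (n == 0L || !any(keep)) {
    stop("stage sequence has no non-artifact segments", call. = FALSE)
  }
  block <- ((seq_len(n) - 1L) %/% block_len_s) + 1L
  n_blocks <- max(block)
  stages <- seq$stages

  blk_n   <- vapply(seq_len(n_blocks), function(b) sum(keep & block == b), 0L)
  blk_b1  <- vapply(seq_len(n_blocks), function(b)
    sum(keep & block == b & stages == "B1"), 0L)
  blk_b23 <- vapply(seq_len(n_blocks), function(b)
    sum(keep & block == b & stages == "B2/3"), 0L)
  blk_c   <- vapply(seq_len(n_blocks), function(b)
    any(keep & block == b & stages == "C"), FALSE)

  frac <- function(num, den) ifelse(den > 0L, num / den, 0)
  block_fractions <- data.frame(
    block = seq_len(n_blocks),
    n_segments = blk_n,
    b1_fraction = frac(blk_b1, blk_n),
    b23_fraction = frac(blk_b23, blk_n))

  c_first <- if (any(blk_c)) which(blk_c)[1L] else NA_integer_

  total <- sum(keep)
  n_high  <- sum(keep & stages %in% c("0", "A1"))
  n_astg  <- sum(keep & stages %in% c("0", "A1", "A2", "A3"))

  score <- NA_integer_
  crit <- NULL
  # scores 1..3: earliest C-containing block
  if (!is.na(c_first) && c_first <= 3L) {
    score <- c_first
    crit <- sprintf(">=1 C stage in block %d (minutes %d-%d)",
                    c_first, (c_first - 1L) * 5L + 1L, c_first * 5L)
  }
  # scores 4..6: B2/3 block fraction >= 1/3, earliest block first
  if (is.na(score)) {
    for (b in seq_len(min(n_blocks, 3L))) {
      if (blk_n[b] > 0L && 3L * blk_b23[b] >= blk_n[b]) {
        score <- 3L + b
        crit <- sprintf(">=1/3 of block %d segments are B2/3", b)
        break
      }
    }
  }
  # scores 7..9: B1 block fraction >= 1/3, earliest block first
  if (is.na(score)) {
    for (b in seq_len(min(n_blocks, 3L))) {
      if (blk_n[b] > 0L && 3L * blk_b1[b] >= blk_n[b]) {
        score <- 6L + b
        crit <- sprintf(">=1/3 of block %d segments are B1", b)
        break
      }
    }
  }
  # score 11, then 10 (2/3-of-all rules, exact rational comparison)
  if (is.na(score) && 3L * n_high >= 2L * total) {
    score <- 11L
    crit <- ">=2/3 of all segments are 0 or A1"
  }
  if (is.na(score) && 3L * n_astg >= 2L * total) {
    score <- 10L
    crit <- ">=2/3 of all segments are 0, A1, A2 or A3"
  }
  if (is.na(score)) {
    score <- as.integer(fallback_score)
    crit <- "fallback: no criterion fired"
  }

  structure(
    list(score = score,
         matched_criterion = crit,
         group = stratify(score),
         block_fractions = block_fractions,
         c_first_block = c_first,
         n_segments_used = total),
    class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("<stability_result> score:", x$score, "(", x$group, ")\n",
      " criterion:", x$matched_criterion, "\n")
  invisible(x)
}

#' Stratify a subject by arousal stability score
#'
#' Subjects whose arousal declines to drowsiness or sleep onset during
#' the 15-min recording (score <= 6) form the hypoaroused fatigue group;
#' scores >= 7 form the non-hypoaroused group.
#'
#' @param score Integer stability score in 1..11.
#' @return `"hypoaroused"` or `"non_hypoaroused"`.
#' @export
stratify <- function(score) {
  if (length(score) != 1L || is.na(score) || score != as.integer(score) ||
      score < 1L || score > 11L) {
    stop("stability score must be a single integer in 1..11", call. = FALSE)
  }
  if (score <= 6L) "hypoaroused" else "non_hypoaroused"
}
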