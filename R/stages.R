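#' Vigilance stage vocabulary
#'
#' Seven EEG vigilance stages ordered from high arousal (stage 0, alert
#' wakefulness with desynchronised low-amplitude beta EEG) down to sleep
#' onset (stage C, marked by sleep spindles or K-complexes). The stage
#' score runs 7 (stage 0) down to 1 (stage C); higher scores mean higher
#' arousal.
#'
#' @format Character vector of the seven stage names in descending arousal
#'   order.
#' @export
VIGILANCE_STAGES <- c("0", "A1", "A2", "A3", "B1", "B2/3", "C")

.STAGE_SCORES <- c("0" = 7L, "A1" = 6L, "A2" = 5L, "A3" = 4L,
                   "B1" = 3L, "B2/3" = 2L, "C" = 1L)

#' Map vigilance stage names to stage scores
#'
#' The fixed bijection 0 -> 7, A1 -> 6, A2 -> 5, A3 -> 4, B1 -> 3,
#' B2/3 -> 2, C -> 1.
#'
#' @param stage Character vector of stage names.
#' @return Integer vector of stage scores (7 = highest arousal).
#' @export
stage_score <- function(stage) {
  bad <- !stage %in% names(.STAGE_SCORES)
  if (any(bad)) {
    stop("unknown vigilance stage token(s): ",
         paste(unique(stage[bad]), collapse = ", "), call. = FALSE)
  }
  unname(.STAGE_SCORES[stage])
}

#' Map stage scores back to stage names
#'
#' @param score Integer vector of stage scores in 1..7.
#' @return Character vector of stage names.
#' @export
stage_from_score <- function(score) {
  if (any(!score %in% 1:7)) {
    stop("stage score must be an integer in 1..7", call. = FALSE)
  }
  names(.STAGE_SCORES)[match(score, .STAGE_SCORES)]
}

#' Construct a per-second stage sequence record
#'
#' Bundles a per-1-s-segment vigilance stage sequence with its artifact
#' mask (TRUE = segment rejected; its stage is a placeholder downstream
#' code must ignore).
#'
#' @param subject_id Subject identifier.
#' @param stages Character vector of stage names, one per 1-s segment.
#' @param artifact_mask Logical vector, same length as `stages`.
#' @return An object of class `stage_sequence`.
#' @export
stage_sequence <- function(subject_id, stages, artifact_mask = NULL) {
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, length(stages))
  if (length(stages) != length(artifact_mask)) {
    stop("stages and artifact_mask must have equal length", call. = FALSE)
  }
  stage_score(stages)  # validates tokens
  structure(
    list(subject_id = as.character(subject_id),
         stages = as.character(stages),
         artifact_mask = as.logical(artifact_mask)),
    class = "stage_sequence")
}

#' @export
print.stage_sequence <- function(x, ...) {
  cat("<stage_sequence> subject:", x$subject_id,
      "| segments:", length(x$stages),
      "| artifact:", sum(x$artifact_mask), "\n")
  tab <- table(factor(x$stages[!x$artifact_mask], levels = VIGILANCE_STAGES))
  print(tab)
  invisible(x)
}

#' @export
length.stage_sequence <- function(x) length(x$stages)
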