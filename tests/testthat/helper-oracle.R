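# Independent brute-force evaluator of the arousal stability criteria:
# a literal transcription of the scoring table, one explicit rule per
# line, kept deliberately separate from the package implementation
# (floating-point fractions here vs exact integer arithmetic there).
oracle_stability <- function(stages, artifact = rep(FALSE, length(stages))) {
  keep <- !artifact
  pos <- seq_along(stages)
  in_block <- function(b) keep & pos > (b - 1) * 300 & pos <= b * 300
  block_frac <- function(b, stage) {
    i <- in_block(b)
    if (sum(i) == 0) return(0)
    sum(stages[i] == stage) / sum(i)
  }
  has_c <- function(b) any(stages[in_block(b)] == "C")
  overall_frac <- function(set) sum(stages[keep] %in% set) / sum(keep)

  if (has_c(1)) return(1)
  if (has_c(2)) return(2)
  if (has_c(3)) return(3)
  if (block_frac(1, "B2/3") >= 1 / 3) return(4)
  if (block_frac(2, "B2/3") >= 1 / 3) return(5)
  if (block_frac(3, "B2/3") >= 1 / 3) return(6)
  if (block_frac(1, "B1") >= 1 / 3) return(7)
  if (block_frac(2, "B1") >= 1 / 3) return(8)
  if (block_frac(3, "B1") >= 1 / 3) return(9)
  if (overall_frac(c("0", "A1")) >= 2 / 3) return(11)
  if (overall_frac(c("0", "A1", "A2", "A3")) >= 2 / 3) return(10)
  10  # fallback
}

# random stage sequences biased toward realistic stage mixes
random_stage_seq <- function(len) {
  probs <- c(0.1, 0.35, 0.1, 0.05, 0.15, 0.2, 0.05)
  sample(VIGILANCE_STAGES, len, replace = TRUE, prob = probs)
}

# exact two-sided Mann-Whitney p by full enumeration of rank
# assignments (no ties): p = min(1, 2 * min(P(U <= u), P(U >= u)))
exact_mw_p <- function(u, n1, n2) {
  N <- n1 + n2
  combos <- utils::combn(N, n1)
  U <- colSums(combos) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(U <= u), mean(U >= u)))
}
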