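#' @name group_stats
#' @title Nonparametric group-comparison battery
#' @description
#' The statistical toolkit for comparing the hypoaroused and
#' non-hypoaroused fatigue groups: Mann-Whitney U with a tie-corrected
#' normal-approximation Z (no continuity correction, matching
#' SPSS-style asymptotic reporting), Pearson chi-square on 2x2 tables,
#' eta-squared effect sizes (Z^2/N) with percentile-bootstrap confidence
#' intervals, and Spearman / partial rank correlations.
NULL

#' Mann-Whitney U test with tie-corrected Z
#'
#' U is computed for the first sample; Z = (U - n1*n2/2) / sd with the
#' tie-corrected standard deviation and no continuity correction, so Z is
#' negative when the first-listed group has the lower mean rank. The
#' two-sided p comes from the normal approximation. With all values
#' identical across both samples the test degenerates to Z = 0, p = 1.
#'
#' @param x,y Numeric samples (first-listed group is `x`).
#' @param eta_n Convention for the eta-squared denominator: "N" (default)
#'   or "N-1".
#' @return List of class `mw_test`: `U` (min of U1, U2, as conventionally
#'   reported), `U1`, `z`, `p`, `eta_squared`, `n1`, `n2`.
#' @export
mann_whitney <- function(x, y, eta_n = c("N", "N-1")) {
  eta_n <- match.arg(eta_n)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty", call. = FALSE)
  N <- n1 + n2
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  sd2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sd2 <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (U1 - mu) / sqrt(sd2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  eta <- eta_squared_mw(z, N, convention = eta_n)
  structure(list(test_name = "mann_whitney",
                 U = min(U1, n1 * n2 - U1), U1 = U1,
                 z = z, p = p, eta_squared = eta, n1 = n1, n2 = n2),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f, Z = %.2f, p = %.3f, eta^2 = %.3f (n = %d/%d)\n",
              x$U, x$z, x$p, x$eta_squared, x$n1, x$n2))
  invisible(x)
}

#' Pearson chi-square on a 2x2 contingency table
#'
#' No continuity correction, df = 1. All four margins must be positive.
#'
#' @param tab 2x2 matrix of counts (rows = groups, columns = outcome).
#' @return List with `statistic`, `p`, `df`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in contingency table", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(test_name = "chi_square", statistic = unname(res$statistic),
       p = unname(res$p.value), df = 1L)
}

#' Eta-squared effect size from a Mann-Whitney Z
#'
#' eta^2 = Z^2 / N (rank-biserial r^2 convention); the alternative
#' Z^2 / (N - 1) is available via `convention`.
#'
#' @param z Normal-approximation Z value.
#' @param n_total Total sample size (>= 2).
#' @param convention "N" (default) or "N-1".
#' @return Numeric eta-squared in [0, 1] for |Z| <= sqrt(N).
#' @export
eta_squared_mw <- function(z, n_total, convention = c("N", "N-1")) {
  convention <- match.arg(convention)
  if (n_total < 2) stop("n_total must be >= 2", call. = FALSE)
  den <- if (convention == "N") n_total else n_total - 1
  z^2 / den
}

#' Percentile-bootstrap confidence interval for a two-sample statistic
#'
#' Groups are resampled independently with replacement, preserving group
#' sizes; the interval is the percentile interval of the statistic over
#' the replicates. Deterministic given `seed`.
#'
#' @param x,y The two samples.
#' @param statistic Function of (x, y) returning a scalar; default is the
#'   Mann-Whitney eta-squared.
#' @param reps Number of bootstrap replicates (default 10000).
#' @param level Confidence level (default 0.90).
#' @param seed Integer seed (required).
#' @return List with `lo`, `hi`, `reps`, `level`, `seed`.
#' @export
bootstrap_ci <- function(x, y,
                         statistic = function(x, y) mann_whitney(x, y)$eta_squared,
                         reps = 10000L, level = 0.90, seed) {
  if (missing(seed)) stop("a seed must be supplied", call. = FALSE)
  force(seed)  # before the state capture: the promise may draw from the RNG
  if (reps < 100L) stop("reps must be >= 100", call. = FALSE)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  vals <- vapply(seq_len(reps), function(i) {
    statistic(sample(x, replace = TRUE), sample(y, replace = TRUE))
  }, numeric(1))
  on.exit(old(), add = TRUE)
  alpha <- (1 - level) / 2
  q <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(lo = q[1], hi = q[2], reps = reps, level = level, seed = seed)
}

# save/restore the global RNG state so bootstrap seeding does not
# perturb a caller's random stream
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Spearman rank correlation with t-approximation p value
#'
#' Average ranks for ties; p from the t distribution with n - 2 degrees
#' of freedom.
#'
#' @param x,y Paired numeric vectors (n >= 3 complete pairs).
#' @return List with `rho`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("constant input vector: Spearman correlation undefined",
         call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- .t_p_from_r(rho, df = n - 2L)
  list(rho = rho, p = p, n = n)
}

.t_p_from_r <- function(r, df) {
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tval), df)
}

#' Partial Spearman correlation
#'
#' All variables (x, y and each covariate) are rank-transformed with
#' average ranks, then x and y are residualised against the covariate
#' ranks by least squares and the Pearson correlation of the residuals is
#' taken. p comes from the t distribution with n - 2 - k degrees of
#' freedom (k = number of covariates). With no covariates this reduces
#' to [spearman()].
#'
#' @param x,y Paired numeric vectors.
#' @param covariates Data frame / matrix of control variables (may be
#'   NULL or zero-column); binary covariates coded 0/1.
#' @return List with `rho`, `p`, `n`, `k`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  cov_m <- if (is.null(covariates)) matrix(numeric(0), nrow = length(x), ncol = 0)
           else as.matrix(covariates)
  keep <- !is.na(x) & !is.na(y) & (ncol(cov_m) == 0 | stats::complete.cases(cov_m))
  x <- x[keep]; y <- y[keep]
  cov_m <- cov_m[keep, , drop = FALSE]
  n <- length(x); k <- ncol(cov_m)
  if (k == 0L) {
    res <- spearman(x, y)
    return(list(rho = res$rho, p = res$p, n = n, k = 0L))
  }
  if (n < k + 3L) stop("too few complete cases", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rc <- apply(cov_m, 2, rank)
  qr_c <- qr(cbind(1, rc))
  if (qr_c$rank < k + 1L) {
    drop_idx <- setdiff(seq_len(k + 1L), qr_c$pivot[seq_len(qr_c$rank)]) - 1L
    nm <- colnames(cov_m)
    nm <- if (is.null(nm)) paste0("covariate_", drop_idx) else nm[drop_idx]
    stop("collinear covariate(s): ", paste(nm, collapse = ", "), call. = FALSE)
  }
  ex <- qr.resid(qr_c, rx)
  ey <- qr.resid(qr_c, ry)
  tol <- 1e-8 * stats::sd(rx)
  if (stats::sd(ex) < tol || stats::sd(ey) < tol) {
    stop("residual variance is zero: partial correlation undefined",
         call. = FALSE)
  }
  rho <- stats::cor(ex, ey)
  p <- .t_p_from_r(rho, df = n - 2L - k)
  list(rho = rho, p = p, n = n, k = k)
}
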