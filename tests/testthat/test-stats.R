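test_that("Mann-Whitney U, Z sign convention and degenerate cases", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  mw <- mann_whitney(x, y)
  expect_equal(mw$U, 0)
  expect_lt(mw$z, 0)  # first-listed group has the lower mean rank
  # full enumeration of the 20 rank assignments gives exact p = 0.1
  expect_equal(exact_mw_p(0, 3, 3), 0.1)
  # antisymmetry
  mw_sw <- mann_whitney(y, x)
  expect_equal(mw_sw$z, -mw$z)
  expect_equal(mw_sw$p, mw$p)
  # identical multisets degenerate to Z = 0, p = 1
  mw_id <- mann_whitney(c(2, 2, 5), c(2, 2, 5))
  expect_equal(mw_id$z, 0)
  expect_equal(mw_id$p, 1)
  expect_error(mann_whitney(numeric(0), y), "non-empty")
})

test_that("tie-corrected Z matches the reference asymptotic test", {
  set.seed(3)
  for (i in 1:20) {
    x <- sample(0:5, 20, replace = TRUE)
    y <- sample(0:6, 15, replace = TRUE)
    if (length(unique(c(x, y))) < 2) next
    mw <- mann_whitney(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(mw$U1, unname(ref$statistic))
    expect_equal(mw$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("asymptotic p error against exact enumeration shrinks with n", {
  # measured envelope of the (no-continuity-correction) normal
  # approximation: the discrepancy decreases in min(n1, n2) and is
  # below 0.05 at n1 = n2 = 8
  max_dp <- function(n1, n2) {
    worst <- 0
    for (u in 0:(n1 * n2)) {
      pex <- exact_mw_p(u, n1, n2)
      mu <- n1 * n2 / 2
      sd <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
      worst <- max(worst, abs(pex - 2 * pnorm(-abs((u - mu) / sd))))
    }
    worst
  }
  expect_lt(max_dp(8, 8), 0.05)
  expect_lt(max_dp(8, 8), max_dp(5, 5))
  expect_lt(max_dp(5, 5), max_dp(3, 3))
})

test_that("chi-square on 2x2 tables: pinned values, zero and scaling laws", {
  suicide <- matrix(c(7, 67, 4, 20), nrow = 2, byrow = TRUE)
  expect_equal(round(chi_square_2x2(suicide)$statistic, 2), 0.94)
  family <- matrix(c(11, 39, 5, 14), nrow = 2, byrow = TRUE)
  expect_equal(round(chi_square_2x2(family)$statistic, 2), 0.14)
  prop <- matrix(c(10, 20, 5, 10), nrow = 2, byrow = TRUE)
  expect_equal(chi_square_2x2(prop)$statistic, 0)
  tab <- matrix(c(8, 12, 5, 15), nrow = 2, byrow = TRUE)
  expect_equal(chi_square_2x2(3 * tab)$statistic,
               3 * chi_square_2x2(tab)$statistic)
  expect_error(chi_square_2x2(matrix(c(0, 0, 4, 20), 2, byrow = TRUE)),
               "margin")
})

test_that("eta-squared from Z", {
  expect_equal(eta_squared_mw(0, 100), 0)
  expect_equal(eta_squared_mw(2, 100), 0.04)
  expect_equal(eta_squared_mw(-2, 100), 0.04)
  expect_equal(eta_squared_mw(2, 101, convention = "N-1"), 0.04)
  expect_error(eta_squared_mw(1, 1), ">= 2")
})

test_that("bootstrap CI: determinism, degenerate data, interval ordering", {
  set.seed(99)
  x <- rnorm(30); y <- rnorm(30, 0.5)
  ci1 <- bootstrap_ci(x, y, reps = 500, seed = 42)
  ci2 <- bootstrap_ci(x, y, reps = 500, seed = 42)
  expect_identical(ci1[c("lo", "hi")], ci2[c("lo", "hi")])
  ci3 <- bootstrap_ci(x, y, reps = 500, seed = 43)
  expect_false(identical(ci1$lo, ci3$lo))
  expect_lte(ci1$lo, ci1$hi)
  const <- bootstrap_ci(rep(2, 10), rep(2, 12), reps = 200, seed = 1)
  expect_equal(const$lo, const$hi)
  expect_error(bootstrap_ci(1, rnorm(5), seed = 1), "at least 2")
  expect_error(bootstrap_ci(rnorm(5), rnorm(5), reps = 50, seed = 1),
               ">= 100")
})

test_that("percentile bootstrap of the mean difference covers near nominal", {
  # 250 null datasets (both groups N(0,1), n = 50): the 90% percentile
  # interval for the mean difference should cover 0 at roughly the
  # nominal rate (small-sample percentile intervals run a little low)
  set.seed(5)
  cover <- 0
  mean_diff <- function(x, y) mean(x) - mean(y)
  for (i in 1:250) {
    x <- rnorm(50); y <- rnorm(50)
    ci <- bootstrap_ci(x, y, statistic = mean_diff, reps = 400,
                       seed = 1000 + i)
    cover <- cover + (ci$lo <= 0 && 0 <= ci$hi)
  }
  expect_gt(cover / 250, 0.85)
  expect_lt(cover / 250, 0.95)
})

test_that("Spearman correlation: exact small cases and error handling", {
  expect_equal(spearman(1:6, c(2, 4, 6, 8, 10, 12))$rho, 1)
  expect_equal(spearman(1:6, -(1:6))$rho, -1)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  # independent computation from the rank-correlation definition
  rx <- rank(x); ry <- rank(y)
  rho_ref <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  res <- spearman(x, y)
  expect_equal(res$rho, rho_ref)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(res$rho, unname(ref$estimate))
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:2, 2:1), "at least 3")
})

test_that("partial Spearman: reduction, degeneracy, structure recovery", {
  set.seed(21)
  x <- rnorm(40); y <- x + rnorm(40)
  plain <- spearman(x, y)
  red <- partial_spearman(x, y, NULL)
  expect_equal(red$rho, plain$rho)
  expect_equal(red$p, plain$p)
  expect_error(partial_spearman(x, y, data.frame(dup = x)),
               "collinear|undefined")
  cvr <- rnorm(40)
  expect_error(
    partial_spearman(x, y, data.frame(a = cvr, b = 2 * cvr)),
    "collinear")
  # y = x + c with x independent of c: controlling for c should push the
  # partial association toward 1, well above the marginal one
  n <- 400
  xx <- rnorm(n); cc <- rnorm(n); yy <- xx + cc
  ps <- partial_spearman(xx, yy, data.frame(c = cc))
  expect_gt(ps$rho, 0.9)
  expect_gt(ps$rho, spearman(xx, yy)$rho)
  # binary covariate coded 0/1 is accepted
  sex <- rbinom(n, 1, 0.5)
  expect_silent(partial_spearman(xx, yy, cbind(c = cc, sex = sex)))
})
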