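# Brute-force oracle: exact two-sided signed-rank p by enumerating all 2^n
# sign assignments on the midranks of |d|.
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= v + 1e-9)
  p_ge <- mean(w_all >= v - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

test_that("exact Wilcoxon matches the sign-enumeration oracle", {
  # all-positive differences at n = 5: p = 2/32
  w <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(w$p_value, 0.0625)
  expect_equal(w$statistic, 15)

  expect_error(wilcoxon_signed_rank(1:4, 1:4), "non-zero")
  expect_message(wilcoxon_signed_rank(c(0, 1, -2, 3, 4)), "dropped 1 zero")

  set.seed(11)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    x <- rnorm(n); y <- rnorm(n)
    if (i > 7) x <- round(x, 1)  # provoke ties in |d|
    d <- x - y
    if (all(d == 0)) next
    expect_equal(wilcoxon_signed_rank(x, y)$p_value, wilcoxon_enum_p(d),
                 tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon agrees with wilcox.test and its normal approximation", {
  set.seed(3)
  for (i in 1:5) {
    d <- rnorm(12)
    ours <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
  # exact and approximate p agree closely at the threshold size
  for (i in 1:10) {
    d <- rnorm(25)
    pe <- wilcoxon_signed_rank(d, exact_threshold = 25)$p_value
    pa <- wilcoxon_signed_rank(d, exact_threshold = 0)$p_value
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("Wilcoxon type-I error is calibrated at the nominal level", {
  set.seed(202)
  n_rep <- 2000
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    x <- rnorm(21); y <- rnorm(21)
    rej[r] <- wilcoxon_signed_rank(x, y)$p_value < 0.05
  }
  expect_gt(mean(rej), 0.035)
  expect_lt(mean(rej), 0.065)
})

test_that("Friedman test matches the tie-corrected rank-formula oracle", {
  friedman_oracle <- function(m) {
    r <- t(apply(m, 1, rank))
    n <- nrow(m); k <- ncol(m)
    rj <- colSums(r)
    a <- sum(r^2); c1 <- n * k * (k + 1)^2 / 4
    (k - 1) * sum((rj - n * (k + 1) / 2)^2) / (a - c1)
  }
  # unanimous ranking reaches the design maximum n(k-1)
  m1 <- matrix(rep(c(1, 3, 2, 4), each = 12), nrow = 12)
  m1 <- m1 + matrix(rnorm(48, sd = 0.01), 12)  # same order, no ties
  f1 <- friedman_rank(m1)
  expect_equal(f1$statistic, friedman_oracle(m1), tolerance = 1e-12)
  expect_equal(f1$statistic, 12 * 3, tolerance = 1e-9)

  # 5 x 3 toy table with ties against the hand formula
  m2 <- matrix(c(1, 2, 2,
                 3, 1, 1,
                 2, 2, 3,
                 1, 1, 2,
                 2, 3, 1), nrow = 5, byrow = TRUE)
  f2 <- friedman_rank(m2)
  expect_equal(f2$statistic, friedman_oracle(m2), tolerance = 1e-12)
  expect_equal(f2$p_value, stats::pchisq(f2$statistic, 2, lower.tail = FALSE))

  expect_error(friedman_rank(matrix(1, 4, 3)), "equally")
})

test_that("Conover post hoc statistics match the published formula", {
  conover_oracle <- function(m) {
    r <- t(apply(m, 1, rank))
    b <- nrow(m); k <- ncol(m)
    rj <- colSums(r)
    a1 <- sum(r^2); c1 <- b * k * (k + 1)^2 / 4
    t1 <- (k - 1) * sum((rj - b * (k + 1) / 2)^2) / (a1 - c1)
    df <- (b - 1) * (k - 1)
    se2 <- 2 * b * (a1 - c1) / df * (1 - t1 / (b * (k - 1)))
    pairs <- utils::combn(k, 2)
    vapply(seq_len(ncol(pairs)), function(q) {
      tstat <- abs(rj[pairs[1, q]] - rj[pairs[2, q]]) / sqrt(se2)
      2 * stats::pt(-tstat, df)
    }, numeric(1))
  }
  set.seed(8)
  m <- matrix(rnorm(24, sd = 1) + rep(c(0, 0.5, 1, 0.2), each = 6), 6, 4)
  got <- conover_posthoc(m)
  expect_equal(nrow(got), 6)
  expect_equal(got$p_value, unname(conover_oracle(m)), tolerance = 1e-12)
  expect_equal(got$p_corrected, pmin(1, got$p_value * 6))

  # identical columns: no pair can differ
  tied <- matrix(rep(rnorm(5), 3), nrow = 5)
  expect_true(all(conover_posthoc(tied)$p_corrected == 1))

  # two conditions: a single pair and no correction factor
  two <- matrix(rnorm(20), 10, 2)
  g2 <- conover_posthoc(two)
  expect_equal(nrow(g2), 1)
  expect_equal(g2$p_corrected, g2$p_value)
})

# Independent JZS oracle: integrate the noncentral-t likelihood against the
# Cauchy prior on the standardized effect (a different parameterization and
# integration variable than the implementation's g-mixture route).
jzs_oracle <- function(t, n, r = sqrt(2) / 2) {
  nu <- n - 1
  f <- function(delta) {
    stats::dt(t, nu, ncp = delta * sqrt(n)) * stats::dcauchy(delta, 0, r)
  }
  num <- suppressWarnings(
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-10, abs.tol = 0)$value)
  num / stats::dt(t, nu)
}

test_that("the JZS Bayes factor matches independent quadrature oracles", {
  for (case in list(c(0, 21), c(1.2, 10), c(2.5, 21), c(-1.8, 15), c(4, 30))) {
    t <- case[1]; n <- case[2]
    bf <- photoddball:::jzs_bf10(t, n)
    expect_equal(bf, jzs_oracle(t, n), tolerance = 1e-6)
  }
  # second integration rule (Gauss-Kronrod on the delta parameterization)
  t <- 2.5; n <- 21; nu <- n - 1
  f <- function(delta) stats::dt(t, nu, ncp = delta * sqrt(n)) * stats::dcauchy(delta, 0, sqrt(2) / 2)
  num <- suppressWarnings(pracma::quadgk(f, -20, 20, tol = 1e-10))
  expect_equal(photoddball:::jzs_bf10(t, n), num / stats::dt(t, nu),
               tolerance = 1e-6)

  # evidence toward the null at t = 0, and monotonicity in |t|
  expect_lt(photoddball:::jzs_bf10(0, 21), 1)
  bfs <- vapply(c(0, 0.5, 1, 1.5, 2, 3), photoddball:::jzs_bf10, numeric(1), n = 21)
  expect_true(all(diff(bfs) > 0))
})

test_that("the paired Bayes factor behaves sensibly on data", {
  set.seed(12)
  x <- rnorm(21, 0, 1); y <- x + rnorm(21, 0, 1)
  b <- bayes_paired_t(x, y)
  tref <- stats::t.test(x, y, paired = TRUE)$statistic
  expect_equal(unname(b$statistic), unname(tref), tolerance = 1e-12)
  expect_error(bayes_paired_t(rep(1, 5), rep(0, 5)), "zero variance")

  # under a true effect d = 0.8 the median BF supports the alternative;
  # under the null it supports nothing
  med_bf <- function(d) {
    stats::median(vapply(1:60, function(i) {
      set.seed(3000 + i)
      bayes_paired_t(rnorm(21, d, 1))$bf10
    }, numeric(1)))
  }
  expect_gt(med_bf(0.8), 3)
  expect_lt(med_bf(0), 1)
})

test_that("Bayes factors are labeled by the stated thresholds", {
  expect_equal(interpret_bf(0.179), "null")
  expect_equal(interpret_bf(1.0), "inconclusive")
  expect_equal(interpret_bf(3.0001), "alternative")
  expect_equal(interpret_bf(c(0.1, 0.5, 10)),
               c("null", "inconclusive", "alternative"))
  expect_error(interpret_bf(-1), "> 0")
})

test_that("Spearman correlation handles monotone, tied and exact cases", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  expect_equal(spearman_cor(x, x^3)$statistic, 1)
  expect_equal(spearman_cor(x, -x)$statistic, -1)

  # tied data against the rank-then-Pearson oracle
  set.seed(5)
  a <- round(rnorm(10), 1); b <- round(rnorm(10), 1)
  got <- spearman_cor(a, b)
  expect_equal(got$statistic, stats::cor(rank(a), rank(b)), tolerance = 1e-12)

  # exact permutation p agrees with cor.test's exact computation (tie-free)
  set.seed(9)
  for (i in 1:3) {
    u <- rnorm(7); v <- rnorm(7)
    ref <- stats::cor.test(u, v, method = "spearman", exact = TRUE)
    expect_equal(spearman_cor(u, v)$p_value, ref$p.value, tolerance = 1e-6)
  }
  expect_error(spearman_cor(rep(1, 5), rnorm(5)), "constant")
  expect_error(spearman_cor(1:2, 2:1), "at least 3")
})

test_that("results tidy into one-row tibbles", {
  w <- wilcoxon_signed_rank(c(0.3, -0.2, 0.5, 0.9, -0.1, 0.4))
  td <- tidy(w)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_true(all(c("method", "statistic", "p_value", "n", "bf10") %in% names(td)))
})
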