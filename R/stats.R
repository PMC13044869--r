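# Statistical tests: exact Wilcoxon signed-rank, Friedman + Conover post
# hoc, JZS Bayesian paired t-test, Spearman correlation, and Bayes-factor
# interpretation.

new_da_test <- function(statistic, p_value, n, method, bf10 = NA_real_,
                        correction = NA_character_, extra = list()) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    rlang::abort("internal error: p-value outside [0, 1]")
  }
  structure(
    c(list(statistic = statistic, p_value = p_value, n = n, method = method,
           bf10 = bf10, correction = correction), extra),
    class = "da_test"
  )
}

#' @export
print.da_test <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.4g, p = %.4g, n = %d", x$method,
              x$statistic, x$p_value, x$n))
  if (!is.na(x$bf10)) cat(sprintf(", BF10 = %.4g (%s)", x$bf10, interpret_bf(x$bf10)))
  cat("\n")
  invisible(x)
}

#' Tidy a test result
#'
#' @param x A `da_test` object.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `statistic`, `p_value`, `n`,
#'   `bf10`.
#' @export
tidy.da_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p_value = x$p_value, n = x$n, bf10 = x$bf10)
}

# Exact null distribution of the signed-rank sum via dynamic programming
# over doubled midranks (so tied ranks stay integral). Returns
# probabilities over W2 = 0 .. sum(2*ranks).
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1L)
  f[1] <- 1
  for (r in ranks2) {
    g <- f / 2
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1:(total + 1L - r)] / 2
    f <- g
  }
  f
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on paired differences. Zero differences are dropped
#' (with a note). For `n <= exact_threshold` retained pairs the p-value
#' is exact, from the full sign-assignment null distribution of the
#' signed-rank sum (computed over midranks, so ties are handled exactly);
#' above the threshold a normal approximation with continuity and tie
#' correction is used.
#'
#' @param x,y Paired samples (`y` omitted tests `x` against zero).
#' @param exact_threshold Largest n for the exact computation (default 25).
#' @return A `da_test` with the signed-rank statistic `V` (sum of ranks
#'   of positive differences).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_threshold = 25L) {
  d <- if (is.null(y)) x else x - y
  zero <- d == 0
  if (any(zero)) {
    rlang::inform(sprintf("wilcoxon_signed_rank: dropped %d zero difference(s)", sum(zero)))
    d <- d[!zero]
  }
  n <- length(d)
  if (n < 2L) rlang::abort("need at least 2 non-zero paired differences")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_threshold) {
    r2 <- as.integer(round(2 * r))
    null <- signed_rank_null(r2)
    w2 <- as.integer(round(2 * v))
    p_le <- sum(null[seq_len(w2 + 1L)])
    p_ge <- sum(null[seq(w2 + 1L, length(null))])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "Wilcoxon signed-rank test (exact)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    zstat <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(zstat)))
    method <- "Wilcoxon signed-rank test (normal approximation)"
  }
  new_da_test(v, p, n, method)
}

#' Friedman rank test for repeated measures
#'
#' Nonparametric test for differences among k conditions measured on the
#' same subjects; wraps [stats::friedman.test()] (within-subject midranks
#' with tie correction) behind the package's result type.
#'
#' @param table Numeric matrix or data frame, subjects x conditions.
#' @return A `da_test` with the chi-squared statistic on k - 1 degrees of
#'   freedom.
#' @export
friedman_rank <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2L || ncol(m) < 2L) rlang::abort("need >= 2 subjects and >= 2 conditions")
  r <- t(apply(m, 1L, rank))
  if (sum((r - mean(r))^2) == 0) {
    rlang::abort("degenerate table: every subject ranks all conditions equally")
  }
  ft <- stats::friedman.test(m)
  new_da_test(unname(ft$statistic), ft$p.value, nrow(m),
              sprintf("Friedman rank test (df = %d)", ncol(m) - 1L),
              extra = list(df = ncol(m) - 1L))
}

#' Conover all-pairs post hoc test after Friedman
#'
#' Pairwise comparisons of condition rank sums using Conover's
#' Friedman-conditional t statistics,
#' `t = |R_i - R_j| / sqrt(2 b (A1 - C1) / ((b-1)(k-1)) * (1 - T1 / (b(k-1))))`
#' on `(b-1)(k-1)` degrees of freedom, where `R_j` are condition rank
#' sums over `b` subjects, `A1` the sum of squared ranks, `C1 = b k
#' (k+1)^2 / 4`, and `T1` the (tie-corrected) Friedman statistic.
#' p-values are Bonferroni-multiplied by the number of pairs and clipped
#' at 1.
#'
#' @param table Numeric matrix or data frame, subjects x conditions.
#' @param bonferroni Apply the Bonferroni correction (default `TRUE`).
#' @return A tibble with one row per pair: `cond_i`, `cond_j`,
#'   `statistic`, `p_value`, `p_corrected`.
#' @export
conover_posthoc <- function(table, bonferroni = TRUE) {
  m <- as.matrix(table)
  b <- nrow(m); k <- ncol(m)
  if (b < 2L || k < 2L) rlang::abort("need >= 2 subjects and >= 2 conditions")
  r <- t(apply(m, 1L, rank))
  rj <- colSums(r)
  a1 <- sum(r^2)
  c1 <- b * k * (k + 1)^2 / 4
  if (a1 == c1) {
    # every subject ranks all conditions equally: no evidence of any
    # pairwise difference
    pairs <- utils::combn(k, 2)
    labs <- colnames(m) %||% as.character(seq_len(k))
    return(tibble::tibble(cond_i = labs[pairs[1, ]], cond_j = labs[pairs[2, ]],
                          statistic = 0, p_value = 1, p_corrected = 1))
  }
  t1 <- (k - 1) * sum((rj - b * (k + 1) / 2)^2) / (a1 - c1)
  df <- (b - 1) * (k - 1)
  denom2 <- 2 * b * (a1 - c1) / df * (1 - t1 / (b * (k - 1)))
  pairs <- utils::combn(k, 2)
  npair <- ncol(pairs)
  labs <- colnames(m) %||% as.character(seq_len(k))
  stat <- p <- numeric(npair)
  for (q in seq_len(npair)) {
    i <- pairs[1, q]; j <- pairs[2, q]
    d <- abs(rj[i] - rj[j])
    if (denom2 <= 0) {
      stat[q] <- if (d > 0) Inf else 0
      p[q] <- if (d > 0) 0 else 1
    } else {
      stat[q] <- d / sqrt(denom2)
      p[q] <- 2 * stats::pt(-stat[q], df)
    }
  }
  factor <- if (bonferroni && npair > 1) npair else 1
  tibble::tibble(
    cond_i = labs[pairs[1, ]], cond_j = labs[pairs[2, ]],
    statistic = stat, p_value = p,
    p_corrected = pmin(1, p * factor)
  )
}

# JZS integrand over the g-prior mixture: Cauchy(0, r) on the
# standardized effect equals Normal(0, g) with g ~ InvGamma(1/2, r^2/2).
jzs_bf10 <- function(t, n, r = sqrt(2) / 2, rel_tol = 1e-10) {
  nu <- n - 1
  log_lik <- function(g) {
    -0.5 * log1p(n * g) - (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu))
  }
  log_prior <- function(g) {
    0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * log(g) - r^2 / (2 * g)
  }
  # substitute g = exp(u) to integrate over the whole real line; guard the
  # far tails where exp(u) overflows (the integrand is 0 there)
  f <- function(u) {
    g <- exp(u)
    val <- exp(log_lik(g) + log_prior(g) + u)
    val[!is.finite(g) | !is.finite(val)] <- 0
    val
  }
  num <- stats::integrate(f, -Inf, Inf, rel.tol = rel_tol, abs.tol = 0)$value
  den <- exp(-(nu + 1) / 2 * log1p(t^2 / nu))
  num / den
}

#' JZS Bayesian paired-samples t-test
#'
#' Bayes factor BF10 for a paired t statistic under the
#' Jeffreys-Zellner-Siow setup: a Cauchy prior (scale `cauchy_scale`,
#' default 0.707) on the standardized effect size under H1, Jeffreys
#' prior on the variance. Computed by adaptive quadrature of the
#' g-mixture representation (relative tolerance 1e-10).
#'
#' @param x,y Paired samples (`y` omitted tests `x` against zero).
#' @param cauchy_scale Cauchy prior scale on the effect size.
#' @return A `da_test` whose `statistic` is the paired t value and whose
#'   `bf10` is the Bayes factor; `p_value` is the classical two-sided
#'   paired-t p for reference.
#' @export
bayes_paired_t <- function(x, y = NULL, cauchy_scale = sqrt(2) / 2) {
  d <- if (is.null(y)) x else x - y
  n <- length(d)
  if (n < 2L) rlang::abort("need at least 2 pairs")
  s <- stats::sd(d)
  if (s == 0) rlang::abort("degenerate data: zero variance of the differences")
  t <- mean(d) / (s / sqrt(n))
  bf <- jzs_bf10(t, n, cauchy_scale)
  new_da_test(t, 2 * stats::pt(-abs(t), n - 1), n,
              sprintf("JZS Bayesian paired t-test (Cauchy scale %.3f)", cauchy_scale),
              bf10 = bf)
}

#' Interpret a Bayes factor
#'
#' `BF10 > 3` is evidence for the alternative, `BF10 < 0.33` evidence for
#' the null; anything between is inconclusive.
#'
#' @param bf10 Bayes factor(s) (> 0).
#' @return Character vector in `{"alternative", "null", "inconclusive"}`.
#' @export
interpret_bf <- function(bf10) {
  if (any(bf10 <= 0)) rlang::abort("Bayes factors must be > 0")
  dplyr::case_when(bf10 > 3 ~ "alternative", bf10 < 0.33 ~ "null",
                   .default = "inconclusive")
}

# All permutations of 1..n as an n! x n integer matrix.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)
    if (pos < n) {
      tmp <- block[, pos]
      block[, pos] <- n
      block[, n] <- tmp
    }
    out[row + seq_len(nrow(sub)), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank ties. For `n <= exact_threshold` the
#' two-sided p-value is exact, by enumeration of all permutations of one
#' variable's ranks; above, it uses the t approximation on
#' `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param x,y Numeric vectors (n >= 3).
#' @param exact_threshold Largest n for permutation enumeration (default 9).
#' @return A `da_test` whose `statistic` is the correlation.
#' @export
spearman_cor <- function(x, y, exact_threshold = 9L) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) rlang::abort("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("correlation undefined for constant input")
  }
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)
  if (n <= exact_threshold) {
    perms <- all_perms(n)
    rs <- apply(matrix(ry[perms], nrow(perms), n), 1L, stats::cor, y = rx)
    p <- mean(abs(rs) >= abs(r) - 1e-12)
    method <- "Spearman rank correlation (exact permutation)"
  } else {
    if (abs(r) >= 1) {
      p <- 0
    } else {
      tval <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tval), n - 2)
    }
    method <- "Spearman rank correlation (t approximation)"
  }
  new_da_test(r, p, n, method)
}
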