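#' One-sample t-test with effect size
#'
#' Two-sided one-sample t-test against zero, returning the t statistic,
#' degrees of freedom, p-value and Hedge's g in a single record. Used by all
#' group-level comparisons (time courses, topographies, quantile pairs).
#'
#' @param x Numeric vector of participant-level values (NAs dropped).
#' @param mu Null value, default 0.
#' @return A list of class `burst_ttest` with elements `t`, `df`, `p`, `g`,
#'   `n`, `mean`, `sd` and a logical `undefined` flag (set when the sample
#'   standard deviation is zero, in which case `t` and `p` are `NA`).
#' @export
one_sample_t <- function(x, mu = 0) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop("one_sample_t() needs at least 2 observations")
  m <- mean(x) - mu
  s <- stats::sd(x)
  if (s == 0) {
    res <- list(t = NA_real_, df = n - 1L, p = NA_real_, g = NA_real_,
                n = n, mean = m, sd = s, undefined = TRUE)
  } else {
    tval <- m / (s / sqrt(n))
    p <- 2 * stats::pt(abs(tval), df = n - 1, lower.tail = FALSE)
    res <- list(t = tval, df = n - 1L, p = p, g = hedges_g(x, mu = mu),
                n = n, mean = m, sd = s, undefined = FALSE)
  }
  class(res) <- "burst_ttest"
  res
}

#' Paired t-test (one-sample t on differences)
#'
#' @param x,y Numeric vectors of equal length; pairs with any NA are dropped.
#' @inherit one_sample_t return
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  one_sample_t(x[keep] - y[keep])
}

#' @export
print.burst_ttest <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g, g = %.3f (n = %d)\n",
              x$df, x$t, x$p, x$g, x$n))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR over one explicit family of p-values. The family is always
#' defined by the calling analysis (per figure or per topography); no global
#' correction is ever applied implicitly.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\] (NAs propagate and are
#'   never significant).
#' @param q FDR level, default 0.05.
#' @return List with `p_fdr` (BH-adjusted p-values) and `significant`
#'   (logical, `p_fdr <= q`).
#' @export
fdr_bh <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p_fdr <- stats::p.adjust(p, method = "BH")
  sig <- !is.na(p_fdr) & p_fdr <= q
  list(p_fdr = p_fdr, significant = sig)
}

#' Hedge's g effect size
#'
#' Bias-corrected standardized mean difference,
#' g = d * J with J = 1 - 3 / (4 df - 1) and df = n - 1. For a single sample
#' d = mean(x - mu) / sd(x); with `y` given the paired differences are used.
#'
#' @param x Numeric vector.
#' @param y Optional second vector for a paired design.
#' @param mu Null value for the one-sample case.
#' @return Hedge's g (scalar).
#' @export
hedges_g <- function(x, y = NULL, mu = 0) {
  if (!is.null(y)) {
    stopifnot(length(x) == length(y))
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep] - y[keep]
    mu <- 0
  } else {
    x <- x[!is.na(x)]
  }
  n <- length(x)
  if (n < 2) stop("hedges_g() needs at least 2 observations")
  s <- stats::sd(x)
  if (s == 0) return(NA_real_)
  d <- (mean(x) - mu) / s
  df <- n - 1
  d * (1 - 3 / (4 * df - 1))
}

#' Minimal detectable standardized effect size
#'
#' Smallest effect size d such that a two-sided one-sample (or paired)
#' t-test with `n` observations attains the requested power at level
#' `alpha`. Power is computed exactly from the noncentral t distribution
#' with noncentrality d * sqrt(n) and df = n - 1, and d is found by root
#' finding. The bias-corrected value on the g scale (d * J) is also
#' returned.
#'
#' @param alpha Two-sided significance level in (0, 1).
#' @param power Target power in (0, 1).
#' @param n Sample size (> 1).
#' @return List with `d` (standardized mean difference scale), `g`
#'   (J-corrected), `alpha`, `power`, `n`, `df`.
#' @examples
#' detectable_effect_size(0.05, 0.8, 18)$d  # about 0.70
#' @export
detectable_effect_size <- function(alpha, power, n) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, n > 1)
  df <- n - 1
  tcrit <- stats::qt(1 - alpha / 2, df)
  pow <- function(d) {
    ncp <- d * sqrt(n)
    stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tcrit, df, ncp = ncp, lower.tail = TRUE) - power
  }
  d <- stats::uniroot(pow, c(1e-8, 20), tol = 1e-10)$root
  J <- 1 - 3 / (4 * df - 1)
  list(d = d, g = d * J, alpha = alpha, power = power, n = n, df = df)
}

#' Achieved power of a one-sample t-test
#'
#' Exact power of a two-sided one-sample t-test at effect size `d`,
#' sample size `n` and level `alpha`, via the noncentral t distribution.
#' Inverse companion of [detectable_effect_size()].
#'
#' @inheritParams detectable_effect_size
#' @param d Standardized effect size.
#' @return Power in (0, 1).
#' @export
t_test_power <- function(d, alpha, n) {
  df <- n - 1
  tcrit <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp, lower.tail = TRUE)
}

#' Lowess smoothing of a regularly sampled series
#'
#' Locally weighted (tricube) linear regression over a fixed time window,
#' as used to smooth event-locked time courses. Exact on globally linear
#' input away from the edges; NA positions are preserved.
#'
#' @param x Numeric series sampled at `rate`.
#' @param rate Sampling rate in Hz.
#' @param span Smoothing window in seconds (default 0.2).
#' @return Smoothed series, same length as `x`.
#' @export
lowess_smooth <- function(x, rate, span = 0.2) {
  stopifnot(span > 0, rate > 0)
  n <- length(x)
  idx <- which(!is.na(x))
  if (length(idx) < 3) return(x)
  k <- span * rate
  if (k < 3) k <- 3
  f <- min(1, k / length(idx))
  sm <- stats::lowess(idx, x[idx], f = f, iter = 0)
  out <- rep(NA_real_, n)
  out[idx] <- sm$y
  out
}

# Vectorised one-sample t over the last margin of a participants x ... array.
# Returns arrays of t, p, g, n with the participant margin dropped.
group_onesample_map <- function(values) {
  stopifnot(is.array(values) || is.matrix(values))
  dm <- dim(values)
  np <- dm[1]
  flat <- matrix(values, nrow = np)
  n <- colSums(!is.na(flat))
  m <- colMeans(flat, na.rm = TRUE)
  s <- apply(flat, 2, stats::sd, na.rm = TRUE)
  tval <- ifelse(n >= 2 & s > 0, m / (s / sqrt(n)), NA_real_)
  p <- 2 * stats::pt(abs(tval), df = pmax(n - 1, 1), lower.tail = FALSE)
  J <- 1 - 3 / (4 * (n - 1) - 1)
  g <- ifelse(n >= 2 & s > 0, (m / s) * J, NA_real_)
  shape <- if (length(dm) > 2) dm[-1] else c(dm[2])
  list(t = array(tval, shape), p = array(p, shape),
       g = array(g, shape), n = array(n, shape),
       mean = array(m, shape))
}
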