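#' Paired t test
#'
#' Textbook paired t on the differences `d = x - y`. A zero-variance,
#' zero-mean difference vector (identical measurements) is reported as
#' t = 0, p = 1 with `degenerate = TRUE`; zero variance around a nonzero
#' mean is an error (the statistic is undefined).
#'
#' @param x,y paired numeric vectors of equal length n >= 2.
#' @return List with `t`, `df`, `p` (two-sided), `mean_diff`, `sd_diff`,
#'   `n`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  d <- x - y
  md <- mean(d)
  sdd <- sd(d)
  if (sdd == 0) {
    if (md == 0)
      return(list(t = 0, df = n - 1L, p = 1, mean_diff = 0, sd_diff = 0,
                  n = n, degenerate = TRUE))
    stop("degenerate: differences have zero variance around a nonzero mean")
  }
  tstat <- md / (sdd / sqrt(n))
  list(t = tstat, df = n - 1L, p = 2 * pt(-abs(tstat), n - 1L),
       mean_diff = md, sd_diff = sdd, n = n, degenerate = FALSE)
}

# internal: two-way ANOVA mean squares of a subjects x raters matrix
twoway_ms <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  gm <- mean(m)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  ssr <- k * sum((rowm - gm)^2)
  ssc <- n * sum((colm - gm)^2)
  sse <- sum((m - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + gm)^2)
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Two-way absolute-agreement average-measures ICC
#'
#' ICC(A,k) in the McGraw-Wong taxonomy: two-way random effects, absolute
#' agreement, mean of k ratings — `(MSR - MSE) / (MSR + (MSC - MSE)/n)` from
#' the two-way ANOVA mean squares. The confidence interval is the F-based
#' single-measure interval (Satterthwaite denominator degrees of freedom)
#' transformed to average measures by the Spearman-Brown relation. A
#' constant matrix (MSR = MSE = 0) is perfect agreement: ICC 1 with a
#' degenerate-CI flag.
#'
#' @param m numeric subjects x raters matrix (>= 2 subjects, >= 2 raters, no
#'   missing cells).
#' @param conf confidence level (default 0.95).
#' @return List with `icc`, `ci` (length 2), `ms` (mean squares),
#'   `degenerate`.
#' @export
icc_a_k <- function(m, conf = 0.95) {
  m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("ratings matrix needs >= 2 subjects and >= 2 raters")
  if (anyNA(m)) stop("missing cells are not supported")
  ms <- twoway_ms(m)
  n <- ms$n
  k <- ms$k
  if (ms$msr == 0 && ms$mse == 0)
    return(list(icc = 1, ci = c(NA_real_, NA_real_), ms = ms,
                degenerate = TRUE))
  icc_k <- (ms$msr - ms$mse) / (ms$msr + (ms$msc - ms$mse) / n)
  # F-based CI for the single-measure form, then Spearman-Brown to k ratings
  icc_1 <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
  alpha <- 1 - conf
  a <- k * icc_1 / (n * (1 - icc_1))
  b <- 1 + k * icc_1 * (n - 1) / (n * (1 - icc_1))
  v <- (a * ms$msc + b * ms$mse)^2 /
    ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
  f_u <- qf(1 - alpha / 2, n - 1, v)
  f_l <- qf(1 - alpha / 2, v, n - 1)
  l1 <- n * (ms$msr - f_u * ms$mse) /
    (f_u * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  u1 <- n * (f_l * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * f_l * ms$msr)
  sb <- function(r) k * r / (1 + (k - 1) * r)
  list(icc = icc_k, ci = c(sb(l1), sb(u1)), ms = ms, degenerate = FALSE)
}

#' Bland-Altman agreement analysis
#'
#' Bias = mean(x - y); limits of agreement = bias +/- 1.96 SD (the
#' conventional normal-quantile multiplier); t-based 95% CIs: for the bias
#' `t * SD / sqrt(n)`, for each limit `t * SD * sqrt(3/n)`.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @param conf confidence level for the CIs (default 0.95).
#' @return An object of class `bland_altman`: list with `bias`, `sd`,
#'   `bias_ci`, `lower_limit`, `lower_ci`, `upper_limit`, `upper_ci`, `n`.
#' @export
bland_altman <- function(x, y, conf = 0.95) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("Bland-Altman needs at least 3 pairs")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  tq <- qt(1 - (1 - conf) / 2, n - 1L)
  lo <- bias - 1.96 * s
  hi <- bias + 1.96 * s
  se_bias <- s / sqrt(n)
  se_lim <- s * sqrt(3 / n)
  structure(list(bias = bias, sd = s,
                 bias_ci = c(bias - tq * se_bias, bias + tq * se_bias),
                 lower_limit = lo, lower_ci = c(lo - tq * se_lim,
                                                lo + tq * se_lim),
                 upper_limit = hi, upper_ci = c(hi - tq * se_lim,
                                                hi + tq * se_lim),
                 n = n),
            class = "bland_altman")
}

#' Exact power of the two-sided paired t test
#'
#' Power at sample size n for detecting a mean paired difference `delta`
#' with SD of differences `sigma`, via the noncentral t distribution with
#' noncentrality `delta/sigma * sqrt(n)`.
#'
#' @param n number of pairs (>= 2).
#' @param delta detectable mean difference.
#' @param sd SD of the paired differences.
#' @param alpha two-sided significance level.
#' @return Power in (0, 1).
#' @export
paired_t_power <- function(n, delta, sd, alpha = 0.05) {
  stopifnot(n >= 2, delta > 0, sd > 0, alpha > 0, alpha < 1)
  ncp <- delta / sd * sqrt(n)
  tc <- qt(1 - alpha / 2, n - 1)
  1 - pt(tc, n - 1, ncp = ncp) + pt(-tc, n - 1, ncp = ncp)
}

#' Paired-design sample size (exact noncentral t)
#'
#' Smallest n >= 2 whose exact two-sided paired t power reaches the target;
#' computed by iterating n upward (no normal approximation — the
#' approximation understates n).
#'
#' @param delta detectable mean difference (> 0).
#' @param sd SD of the paired differences (> 0).
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.80).
#' @return Integer sample size.
#' @export
paired_sample_size <- function(delta, sd, alpha = 0.05, power = 0.80) {
  stopifnot(delta > 0, sd > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  n <- 2L
  repeat {
    if (paired_t_power(n, delta, sd, alpha) >= power) return(n)
    n <- n + 1L
    if (n > 1e6) stop("sample size search did not converge")
  }
}
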