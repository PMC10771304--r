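#' Pooled-variance two-sample t-test p-value
#'
#' Two-sided Student t-test with pooled variance (not Welch): at n = 3
#' per group there is no information to estimate separate variances and
#' the classical pooled form is the convention of integrated-testing
#' pipelines. Degenerate inputs are resolved before delegating to
#' [stats::t.test()]: zero pooled variance with equal means gives p = 1,
#' zero pooled variance with unequal means gives the p-value floor.
#'
#' @param a,b numeric vectors, length >= 2, finite.
#' @param welch use Welch's unequal-variance form instead.
#' @return Two-sided p-value in (0, 1].
#' @export
t_test_pvalue <- function(a, b, welch = FALSE) {
  check_two_groups(a, b)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (mean(a) == mean(b)) 1 else 1e-15)
  stats::t.test(a, b, var.equal = !welch)$p.value
}

check_two_groups <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs >= 2 values", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("non-finite values in input", call. = FALSE)
  invisible(NULL)
}

#' Wilcoxon rank-sum p-value, exact by enumeration when feasible
#'
#' Two-sided rank-sum test. When the data are tie-free and the number of
#' distinct group-label assignments `choose(na+nb, na)` is at most
#' 10,000, the p-value is exact: all assignments are enumerated and the
#' rank-sum's deviation from its null mean is compared against the
#' observed one. Otherwise the normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param a,b numeric vectors, length >= 2.
#' @return Two-sided p-value in (0, 1].
#' @export
ranksum_pvalue <- function(a, b) {
  check_two_groups(a, b)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) return(1)
  na <- length(a); n <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && n_assignments(n, na) <= 10000) {
    idx <- enumerate_assignments(n, na)
    w_all <- colSums(matrix(r[idx], nrow = na))
    return(mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12))
  }
  nb <- n - na
  tab <- table(pooled)
  tie_term <- sum(tab^3 - tab) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (w_obs - mu - 0.5 * sign(w_obs - mu)) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Median-difference permutation test
#'
#' Permutation test on `T = median(a) - median(b)`. All distinct label
#' reassignments are enumerated when their number is at most 10,000
#' (e.g. the 20 assignments of a 3-vs-3 design), giving
#' `p = #\{|T*| >= |T|\} / N`; larger designs fall back to seeded
#' Monte-Carlo with the add-one correction
#' `p = (#\{|T*| >= |T|\} + 1) / (N + 1)`.
#'
#' @param a,b numeric vectors, length >= 2.
#' @param n_mc Monte-Carlo draws when enumeration is infeasible.
#' @param seed seed for the Monte-Carlo fallback.
#' @return A list with `p` (p-value) and `sign` (sign of the observed
#'   median difference: +1, -1 or 0).
#' @export
median_diff_pvalue <- function(a, b, n_mc = 10000, seed = 1) {
  check_two_groups(a, b)
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  t_obs <- stats::median(a) - stats::median(b)
  if (n_assignments(n, na) <= 10000) {
    idx <- enumerate_assignments(n, na)
    t_all <- apply(idx, 2L, function(ia)
      stats::median(pooled[ia]) - stats::median(pooled[-ia]))
    p <- mean(abs(t_all) >= abs(t_obs) - 1e-12)
  } else {
    set.seed(seed)
    hits <- 0L
    for (k in seq_len(n_mc)) {
      ia <- sample.int(n, na)
      if (abs(stats::median(pooled[ia]) - stats::median(pooled[-ia])) >=
          abs(t_obs) - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_mc + 1)
  }
  list(p = p, sign = sign(t_obs))
}

#' Combine three p-values by Stouffer's method with a common direction
#'
#' Each two-sided p-value is mapped to a normal score
#' `z_i = sign * qnorm(1 - p_i / 2)` carrying one common direction (the
#' median-difference sign: the three tests address the same contrast, so
#' discordant per-test signs would cancel meaninglessly), the scores are
#' summed and scaled by `1/sqrt(3)`, and the combined two-sided p is
#' read off the normal distribution. P-values are clipped to
#' `[1e-15, 1 - 1e-15]` before the quantile transform for numeric
#' stability.
#'
#' @param pvalues numeric vector of three two-sided p-values in (0, 1].
#' @param sign common direction, +1, -1 or 0.
#' @return A list with `z_comb` and `p_comb`.
#' @examples
#' stouffer_combine(c(0.5, 0.5, 0.5), sign = 1)
#' @export
stouffer_combine <- function(pvalues, sign) {
  if (length(pvalues) != 3L)
    stop("expected exactly three p-values", call. = FALSE)
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  if (!sign %in% c(-1, 0, 1))
    stop("sign must be +1, -1 or 0", call. = FALSE)
  p <- clip_pvalue(pvalues)
  z <- sign * stats::qnorm(1 - p / 2)
  z_comb <- sum(z) / sqrt(3)
  list(z_comb = z_comb, p_comb = 2 * stats::pnorm(-abs(z_comb)))
}

#' Storey q-values with smoother pi0 estimation
#'
#' Estimates the null proportion pi0 by evaluating
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` on the grid
#' `lambda = 0.05, 0.10, ..., 0.95`, smoothing with a natural cubic
#' spline (3 df) and reading off the fit at the largest lambda, clipped
#' to (0, 1]. For fewer than 100 p-values the tail of the p-value
#' histogram carries too little information and pi0 falls back to 1, in
#' which case (or with `pi0 = 1` forced) the result equals
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param pi0 optional forced null proportion in (0, 1]; `NULL` (default)
#'   estimates it.
#' @return Numeric vector of q-values, input order, with attribute
#'   `pi0`.
#' @export
storey_qvalues <- function(pvalues, pi0 = NULL) {
  m <- length(pvalues)
  if (m == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (is.null(pi0)) {
    pi0 <- if (m < 100) 1 else estimate_pi0_smoother(pvalues)
  } else if (!(is.numeric(pi0) && pi0 > 0 && pi0 <= 1)) {
    stop("pi0 must lie in (0, 1]", call. = FALSE)
  }
  o <- order(pvalues)
  q_sorted <- pi0 * m * pvalues[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  attr(q, "pi0") <- pi0
  q
}

estimate_pi0_smoother <- function(pvalues) {
  m <- length(pvalues)
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_l <- vapply(lambda, function(l) sum(pvalues > l) / (m * (1 - l)),
                  numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, 1e-8), 1)
}

#' Log2 ratio of group medians
#'
#' The effect-size statistic of the DEG rule. On log2-scale data it is
#' the difference of group medians; on linear-scale data the log2 of
#' their ratio (requiring positive medians).
#'
#' @param a,b numeric vectors (treated, control).
#' @param scale `"log2"` or `"linear"`.
#' @return The log2-median-ratio, treated relative to control.
#' @export
log2_median_ratio <- function(a, b, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  ma <- stats::median(a); mb <- stats::median(b)
  if (scale == "log2") return(ma - mb)
  if (ma <= 0 || mb <= 0)
    stop("linear-scale medians must be positive for a log2 ratio",
         call. = FALSE)
  log2(ma / mb)
}
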