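#' Spearman rank correlation with exact small-sample p-value
#'
#' Rho is the Pearson correlation of mid-ranks (tie-safe). The two-tailed
#' p-value is exact for n <= 9 tie-free data — all n! rank permutations
#' are enumerated and `p = #\{|rho*| >= |rho|\} / n!` — and otherwise
#' uses the t approximation `t = rho sqrt((n-2) / (1-rho^2))` on n-2
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A list with `rho`, `p`, `n`.
#' @examples
#' spearman(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y differ in length", call. = FALSE)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in input", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Spearman correlation undefined", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  tie_free <- !anyDuplicated(x) && !anyDuplicated(y)
  if (n <= 9L && tie_free) {
    ## rho* is affine in the cross-sum: with tie-free ranks,
    ## rho* = (sum(rx * q) - n ((n+1)/2)^2) / (n (n^2 - 1) / 12)
    perms <- all_permutations(n)
    s_all <- as.numeric(perms %*% rx)
    mu <- n * (n + 1)^2 / 4
    denom <- n * (n^2 - 1) / 12
    rho_all <- (s_all - mu) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- if (n <= 2) 1 else 2 / factorial(min(n, 171))
      p <- min(p, 1)
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p = min(p, 1), n = n)
}

## All permutations of 1..n as an n!-by-n matrix (n <= 9).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, ] <- cbind(sub + (sub >= k), k)
  }
  out
}

#' Stratified driver-vs-signature Spearman association
#'
#' For each stratum (plus the pooled pseudo-stratum `"all"`) and each
#' signature, computes the Spearman correlation between a driver gene's
#' expression and the per-sample signature scores — the analysis that
#' asks whether, e.g., high sterol-hydroxylase expression tracks low
#' DNA-repair signature activity across a cohort. Driver expression is
#' taken from the standardized matrix used for scoring; Spearman is
#' invariant under that monotone transform. Strata with fewer than
#' `min_n` samples are reported as skipped rather than yielding an
#' unstable p-value.
#'
#' @param em the [expr_matrix()] the scores were computed from.
#' @param driver_gene gene identifier present in `em`.
#' @param scores score table from [score_signatures()].
#' @param stratum_key annotation key holding stratum labels (default
#'   `"stratum"`); `NULL` for no stratification beyond `"all"`.
#' @param min_n minimum stratum size for a reported correlation.
#' @return A `data.frame` with columns `stratum`, `signature`, `n`,
#'   `rho`, `p`, `skipped`, `reason`.
#' @export
correlate_driver_with_signatures <- function(em, driver_gene, scores,
                                             stratum_key = "stratum",
                                             min_n = 10) {
  stopifnot(inherits(em, "expr_matrix"), is.data.frame(scores))
  if (!driver_gene %in% gene_ids(em))
    stop("driver gene '", driver_gene, "' not in matrix", call. = FALSE)
  std <- suppressWarnings(median_center_scale(em))
  if (!driver_gene %in% gene_ids(std))
    stop("driver gene '", driver_gene, "' has zero variance", call. = FALSE)
  driver <- stats::setNames(std$values[driver_gene, ], sample_ids(std))
  strata <- if (!is.null(stratum_key))
    annotation_column(em, stratum_key)
  else
    stats::setNames(rep("all", ncol(em$values)), sample_ids(em))
  stratum_levels <- unique(c("all", sort(unique(unname(strata)))))
  rows <- list()
  for (st in stratum_levels) {
    in_st <- if (st == "all") names(strata) else names(strata)[strata == st]
    for (sig in unique(scores$signature)) {
      d <- scores[scores$signature == sig, ]
      common <- intersect(intersect(d$sample_id, names(driver)), in_st)
      n <- length(common)
      if (n < min_n) {
        log_msg("stratum '", st, "', signature '", sig,
                "' skipped: n = ", n, " < ", min_n, level = "WARN")
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = st, signature = sig, n = n, rho = NA_real_,
          p = NA_real_, skipped = TRUE,
          reason = sprintf("n < %d", min_n), stringsAsFactors = FALSE)
        next
      }
      sc <- stats::setNames(d$score, d$sample_id)[common]
      sp <- spearman(driver[common], sc)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, signature = sig, n = n, rho = sp$rho, p = sp$p,
        skipped = FALSE, reason = "", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
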