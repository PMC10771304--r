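#' Permutation null of the absolute log2-median-ratio
#'
#' Builds the genome-wide null used as the DEG effect-size filter: for
#' each permutation of the two-group sample labels the per-gene absolute
#' log2-median-ratio is computed, values are pooled across genes and
#' permutations, and the threshold is the 95th percentile
#' (nearest-rank) of the pool. When the number of distinct label
#' assignments is at most `n_perm` they are enumerated exhaustively (a
#' 3-vs-3 design has exactly 20); otherwise `n_perm` seeded assignments
#' are drawn, the identity assignment always included as the
#' conservative convention.
#'
#' @param em an [expr_matrix()].
#' @param labels per-sample group labels (two levels), aligned with the
#'   matrix columns.
#' @param n_perm permutation budget (default 1000).
#' @param seed seed for the Monte-Carlo branch.
#' @param treated label of the treated group (see [resolve_groups]
#'   conventions); only the assignment geometry matters here.
#' @param prob percentile of the pooled null used as threshold.
#' @return An object of class `permutation_null`: list with
#'   `pooled_abs_lmr`, `threshold`, `n_perm` (effective count),
#'   `exhaustive`, `seed`.
#' @export
permutation_null_lmr <- function(em, labels = NULL, n_perm = 1000,
                                 seed = 1, treated = NULL, prob = 0.95) {
  stopifnot(inherits(em, "expr_matrix"))
  labels <- labels %||% annotation_column(em, "group")
  grp <- resolve_groups(labels, treated)
  n <- ncol(em$values)
  if (length(labels) != n)
    stop("labels do not match the number of samples", call. = FALSE)
  n_a <- sum(labels == grp[["treated"]])
  if (n_a < 2L || n - n_a < 2L)
    stop("each group needs >= 2 samples", call. = FALSE)
  total <- n_assignments(n, n_a)
  if (total < 2)
    stop("fewer than 2 distinct label assignments", call. = FALSE)
  exhaustive <- total <= n_perm
  if (exhaustive) {
    idx <- enumerate_assignments(n, n_a)
  } else {
    set.seed(seed)
    idx <- matrix(0L, n_a, n_perm)
    idx[, 1L] <- which(labels == grp[["treated"]])  # identity assignment
    for (k in 2:n_perm) idx[, k] <- sample.int(n, n_a)
  }
  pooled <- as.numeric(vapply(seq_len(ncol(idx)), function(k) {
    ia <- idx[, k]
    med_a <- apply(em$values[, ia, drop = FALSE], 1L, stats::median)
    med_b <- apply(em$values[, -ia, drop = FALSE], 1L, stats::median)
    if (em$scale == "log2") abs(med_a - med_b) else abs(log2(med_a / med_b))
  }, numeric(nrow(em$values))))
  structure(list(pooled_abs_lmr = pooled,
                 threshold = nearest_rank(pooled, prob),
                 n_perm = ncol(idx), exhaustive = exhaustive,
                 seed = as.integer(seed)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "permutation_null: %d %s permutations, %d pooled |lmr| values, threshold %.4g\n",
    x$n_perm, if (x$exhaustive) "exhaustive" else "Monte-Carlo",
    length(x$pooled_abs_lmr), x$threshold))
  invisible(x)
}

#' Integrated hypothesis-testing DEG caller
#'
#' The central caller for small-sample two-condition designs. Per gene,
#' three p-values are computed — pooled-variance t-test, rank-sum test,
#' and median-difference permutation test — and combined by Stouffer's
#' method under the common median-difference direction; q-values over
#' all genes come from Storey's method; and a gene is called
#' differentially expressed when its q-value falls below `fdr_cut` AND
#' its absolute log2-median-ratio exceeds the 95th-percentile threshold
#' of the pooled permutation null (see [permutation_null_lmr()]).
#'
#' @param em an [expr_matrix()].
#' @param labels optional per-sample group labels; defaults to the
#'   `group` annotation column.
#' @param treated label of the treated group; defaults to `"treated"`
#'   when present, else the first sorted label.
#' @param fdr_cut q-value cutoff (default 0.05).
#' @param n_perm permutation budget for the lmr null (default 1000).
#' @param seed seed for all stochastic stages.
#' @param welch use Welch instead of pooled-variance t-tests.
#' @return A list with `deg` — a `data.frame` (one row per gene, input
#'   order) with columns `gene_id`, `p_t`, `p_rs`, `p_md`, `sign`,
#'   `z_comb`, `p_comb`, `q`, `lmr`, `is_deg` — and `null`, the
#'   [permutation_null_lmr()] object; `pi0` is carried as an attribute
#'   of the `deg` table.
#' @examples
#' sim <- generate_de_experiment(
#'   de_plant_spec(n_genes = 120, n_de = 12, seed = 5))
#' res <- run_integrated_deg(sim$matrix, seed = 5)
#' table(called = res$deg$is_deg, planted = sim$truth$is_de)
#' @export
run_integrated_deg <- function(em, labels = NULL, treated = NULL,
                               fdr_cut = 0.05, n_perm = 1000, seed = 1,
                               welch = FALSE) {
  stopifnot(inherits(em, "expr_matrix"))
  if (!(is.numeric(fdr_cut) && fdr_cut > 0 && fdr_cut < 1))
    stop("fdr_cut must lie in (0, 1)", call. = FALSE)
  labels <- labels %||% annotation_column(em, "group")
  grp <- resolve_groups(labels, treated)
  ia <- which(labels == grp[["treated"]])
  ib <- which(labels == grp[["control"]])
  ng <- nrow(em$values)
  gid <- gene_ids(em)
  p_t <- p_rs <- p_md <- sgn <- lmr <- z_comb <- p_comb <- numeric(ng)
  for (g in seq_len(ng)) {
    a <- em$values[g, ia]; b <- em$values[g, ib]
    res <- tryCatch({
      pt <- t_test_pvalue(a, b, welch = welch)
      prs <- ranksum_pvalue(a, b)
      md <- median_diff_pvalue(a, b, seed = seed)
      comb <- stouffer_combine(c(pt, prs, md$p), sign = md$sign)
      list(pt = pt, prs = prs, pmd = md$p, sgn = md$sign,
           z = comb$z_comb, p = comb$p_comb,
           lmr = log2_median_ratio(a, b, scale = em$scale))
    }, error = function(e)
      stop("gene '", gid[g], "': ", conditionMessage(e), call. = FALSE))
    p_t[g] <- res$pt; p_rs[g] <- res$prs; p_md[g] <- res$pmd
    sgn[g] <- res$sgn; z_comb[g] <- res$z; p_comb[g] <- res$p
    lmr[g] <- res$lmr
  }
  q <- storey_qvalues(p_comb)
  null <- permutation_null_lmr(em, labels = labels, n_perm = n_perm,
                               seed = seed, treated = treated)
  log_msg(sprintf(
    "integrated DEG: %d genes, %s null (%d permutations), |lmr| threshold %.4f, pi0 %.3f",
    ng, if (null$exhaustive) "exhaustive" else "Monte-Carlo",
    null$n_perm, null$threshold, attr(q, "pi0")))
  deg <- data.frame(gene_id = gid, p_t = p_t, p_rs = p_rs, p_md = p_md,
                    sign = sgn, z_comb = z_comb, p_comb = p_comb,
                    q = as.numeric(q), lmr = lmr,
                    is_deg = as.numeric(q) < fdr_cut &
                      abs(lmr) > null$threshold,
                    stringsAsFactors = FALSE)
  attr(deg, "pi0") <- attr(q, "pi0")
  list(deg = deg, null = null)
}
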