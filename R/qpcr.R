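#' Delta-delta-Ct relative quantification
#'
#' Standard relative quantification for qPCR validation data. Technical
#' replicates are averaged on the Ct scale per (sample, gene); per
#' sample, `dCt = Ct_target - Ct_housekeeping` (with two housekeeping
#' genes, their mean Ct); the group fold change is
#' `2^-(mean dCt treated - mean dCt control)`, and per-sample relative
#' levels are `2^-(dCt - mean control dCt)`, so the control group's mean
#' relative level is 1 by construction.
#'
#' @param table long-format `data.frame` with columns `sample_id`,
#'   `group`, `gene_id`, `replicate`, `ct` (see [generate_qpcr()]).
#' @param target target gene identifier.
#' @param housekeeping one or two housekeeping gene identifiers;
#'   multiple genes are averaged per sample.
#' @param treated label of the treated group.
#' @return A list with `per_sample` (`data.frame` of `sample_id`,
#'   `group`, `dct`, `rel_level`), `fold_change` (treated vs control),
#'   `ddct`, and `group_p` — the two-sided pooled-variance t-test on the
#'   per-sample dCt values (equivalently log2 relative levels, where the
#'   variance is homogeneous).
#' @examples
#' tab <- generate_qpcr(planted_fold = 0.5, ct_sd = 0.05, seed = 2)
#' delta_delta_ct(tab, "TARGET1", "GAPDH")$fold_change
#' @export
delta_delta_ct <- function(table, target, housekeeping,
                           treated = NULL) {
  need <- c("sample_id", "group", "gene_id", "replicate", "ct")
  stopifnot(is.data.frame(table), all(need %in% names(table)))
  if (any(table$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  grp <- resolve_groups(table$group, treated)
  ## mean Ct per (sample, gene) over technical replicates
  agg <- stats::aggregate(ct ~ sample_id + group + gene_id, data = table,
                          FUN = mean)
  samples <- unique(agg$sample_id)
  dct <- vapply(samples, function(s) {
    d <- agg[agg$sample_id == s, ]
    tgt <- d$ct[d$gene_id == target]
    hk <- d$ct[d$gene_id %in% housekeeping]
    if (length(tgt) != 1L)
      stop("sample '", s, "': target '", target, "' not measured",
           call. = FALSE)
    if (!length(hk))
      stop("sample '", s, "': no housekeeping measurement", call. = FALSE)
    tgt - mean(hk)
  }, numeric(1))
  group_of <- vapply(samples, function(s)
    as.character(agg$group[agg$sample_id == s][1L]), character(1))
  if (!all(c(grp) %in% group_of))
    stop("both groups must be non-empty", call. = FALSE)
  dct_t <- dct[group_of == grp[["treated"]]]
  dct_c <- dct[group_of == grp[["control"]]]
  ddct <- mean(dct_t) - mean(dct_c)
  per_sample <- data.frame(sample_id = samples, group = group_of,
                           dct = as.numeric(dct),
                           rel_level = 2^-(dct - mean(dct_c)),
                           stringsAsFactors = FALSE, row.names = NULL)
  list(per_sample = per_sample,
       ddct = ddct,
       fold_change = 2^-ddct,
       group_p = if (length(dct_t) >= 2 && length(dct_c) >= 2)
         t_test_pvalue(dct_t, dct_c) else NA_real_)
}

#' Two-sample comparison of small measurement groups
#'
#' Two-sided pooled-variance t-test with the mean difference, reusable
#' for relative expression levels, percent-tail-DNA summaries, or any
#' small two-group measurement table. Zero variance in both groups with
#' equal means yields p = 1.
#'
#' @param values_a,values_b numeric vectors, each length >= 2.
#' @return A list with `mean_diff` (a minus b) and `p`.
#' @export
group_compare <- function(values_a, values_b) {
  check_two_groups(values_a, values_b)
  list(mean_diff = mean(values_a) - mean(values_b),
       p = t_test_pvalue(values_a, values_b))
}
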