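#' Median-center and SD-scale an expression matrix
#'
#' Standardizes each gene across samples: subtract the across-sample
#' median, divide by the across-sample standard deviation. This is the
#' substrate of weighted Z-score signature scoring. Zero-variance genes
#' carry no ranking information and are dropped with a warning.
#'
#' @param em an [expr_matrix()] with >= 2 samples.
#' @return An [expr_matrix()] of standardized values (same scale tag,
#'   annotations preserved), possibly with fewer genes.
#' @export
median_center_scale <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  if (ncol(em$values) < 2L)
    stop("standardization needs >= 2 samples", call. = FALSE)
  med <- apply(em$values, 1L, stats::median)
  sd_ <- apply(em$values, 1L, stats::sd)
  zero <- sd_ == 0
  if (any(zero))
    warning("dropping ", sum(zero), " zero-variance gene(s): ",
            paste(utils::head(gene_ids(em)[zero], 5), collapse = ", "),
            if (sum(zero) > 5) ", ..." else "", call. = FALSE)
  z <- (em$values - med) / sd_
  z <- z[!zero, , drop = FALSE]
  out <- expr_matrix(z, scale = em$scale)
  out$annotations <- em$annotations
  out
}

#' Weighted Z-score of one gene set per sample
#'
#' For sample j the enrichment score over the matched genes i of the set
#' is `sum_i w_i z_ij / sqrt(sum_i w_i^2)`, with z the standardized
#' expression and w the +1/-1 direction weights. A set with no matched
#' gene yields `NULL` (a skip, distinct from a numeric zero).
#'
#' @param standardized an [expr_matrix()] from [median_center_scale()].
#' @param geneset a [gene_set()].
#' @return Named numeric vector of per-sample scores with attributes
#'   `n_found` and `coverage`, or `NULL` when no gene matches.
#' @export
weighted_zscore <- function(standardized, geneset) {
  stopifnot(inherits(standardized, "expr_matrix"),
            inherits(geneset, "gene_set"))
  hit <- geneset$genes %in% gene_ids(standardized)
  if (!any(hit)) return(NULL)
  z <- standardized$values[geneset$genes[hit], , drop = FALSE]
  w <- geneset$weights[hit]
  scores <- as.numeric(crossprod(z, w)) / sqrt(sum(w^2))
  names(scores) <- sample_ids(standardized)
  attr(scores, "n_found") <- sum(hit)
  attr(scores, "coverage") <- sum(hit) / length(geneset$genes)
  scores
}

#' Score a collection of signatures on an expression matrix
#'
#' Standardizes once ([median_center_scale()]) and computes the weighted
#' Z-score of every gene set for every sample. Sets without any matched
#' gene are skipped with a message and are absent from the result —
#' never reported as zero.
#'
#' @param em an [expr_matrix()].
#' @param genesets a list of [gene_set()] objects with unique names.
#' @return A `data.frame` with columns `signature`, `sample_id`,
#'   `score`, `n_found`, `coverage`.
#' @export
score_signatures <- function(em, genesets) {
  stopifnot(inherits(em, "expr_matrix"), length(genesets) > 0)
  nm <- vapply(genesets, function(g) g$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate signature name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  std <- median_center_scale(em)
  rows <- list()
  skipped <- character(0)
  for (gs in genesets) {
    sc <- weighted_zscore(std, gs)
    if (is.null(sc)) {
      skipped <- c(skipped, gs$name)
      log_msg("signature '", gs$name, "' skipped: no genes in matrix",
              level = "WARN")
      next
    }
    rows[[gs$name]] <- data.frame(
      signature = gs$name, sample_id = names(sc), score = as.numeric(sc),
      n_found = attr(sc, "n_found"), coverage = attr(sc, "coverage"),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!length(rows))
    stop("no signature matched the matrix: ",
         paste(skipped, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "skipped") <- skipped
  out
}

#' Compare signature scores between two groups
#'
#' Per signature, a two-sided pooled-variance t-test of the per-sample
#' scores between two groups, reporting the treated-minus-control mean
#' difference — the comparison behind claims that a treatment
#' down-regulates a gene program (negative difference = lower signature
#' activity under treatment).
#'
#' @param scores a score table from [score_signatures()].
#' @param labels named character vector mapping `sample_id` to group, or
#'   an annotation `data.frame` with `sample_id` and `group` columns.
#' @param treated label of the treated group.
#' @return A `data.frame` with columns `signature`, `n_treated`,
#'   `n_control`, `mean_diff`, `p`.
#' @export
signature_group_test <- function(scores, labels, treated = NULL) {
  stopifnot(is.data.frame(scores),
            all(c("signature", "sample_id", "score") %in% names(scores)))
  if (is.data.frame(labels)) {
    stopifnot(all(c("sample_id", "group") %in% names(labels)))
    labels <- stats::setNames(as.character(labels$group), labels$sample_id)
  }
  grp <- resolve_groups(labels, treated)
  out <- lapply(split(scores, scores$signature), function(d) {
    g <- labels[d$sample_id]
    if (any(is.na(g)))
      stop("unlabelled sample(s): ",
           paste(d$sample_id[is.na(g)], collapse = ", "), call. = FALSE)
    a <- d$score[g == grp[["treated"]]]
    b <- d$score[g == grp[["control"]]]
    if (length(a) < 2L || length(b) < 2L)
      stop("signature '", d$signature[[1L]],
           "': each group needs >= 2 scored samples", call. = FALSE)
    data.frame(signature = d$signature[[1L]],
               n_treated = length(a), n_control = length(b),
               mean_diff = mean(a) - mean(b),
               p = t_test_pvalue(a, b), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(unname(out), list(make.row.names = FALSE)))
}
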