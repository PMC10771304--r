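#' Expression matrix container
#'
#' A lightweight genes-by-samples container for normalized expression
#' values, the substrate of DEG calling, signature scoring and
#' driver-signature association. Values are a plain numeric matrix with
#' gene identifiers as row names and sample identifiers as column names;
#' per-sample annotations (group, stratum, ...) ride along as a
#' `data.frame` keyed by `sample_id`.
#'
#' Identifiers are opaque case-sensitive strings; duplicates are
#' rejected, as are non-finite values — the downstream statistics assume
#' complete matrices, so missing data is an input error, never imputed.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   complete `dimnames`.
#' @param scale `"log2"` or `"linear"`; declares the scale the values are
#'   on, which controls how the log2-median-ratio is computed.
#' @param annotations optional `data.frame` with a `sample_id` column
#'   covering every sample in `values`.
#' @return An object of class `expr_matrix`: a list with elements
#'   `values`, `scale` and `annotations`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expr_matrix(m, scale = "log2")
#' dim(em)
#' @export
expr_matrix <- function(values, scale = c("log2", "linear"),
                        annotations = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene row names and sample column names",
         call. = FALSE)
  dup_g <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(unique(dup_g), collapse = ", "),
         call. = FALSE)
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("'values' contains non-finite entries", call. = FALSE)
  em <- structure(list(values = values, scale = scale, annotations = NULL),
                  class = "expr_matrix")
  if (!is.null(annotations)) em <- attach_annotations(em, annotations)
  em
}

#' Attach a sample annotation table to an expression matrix
#'
#' @param em an [expr_matrix()].
#' @param annotations `data.frame` with a `sample_id` column; every sample
#'   of `em` must be present (extra rows are dropped).
#' @return `em` with annotations attached, rows ordered as the samples.
#' @export
attach_annotations <- function(em, annotations) {
  stopifnot(inherits(em, "expr_matrix"))
  if (!is.data.frame(annotations) || !"sample_id" %in% names(annotations))
    stop("annotations must be a data.frame with a 'sample_id' column",
         call. = FALSE)
  if (anyDuplicated(annotations$sample_id))
    stop("duplicate sample_id in annotations", call. = FALSE)
  missing <- setdiff(colnames(em$values), annotations$sample_id)
  if (length(missing))
    stop("annotations missing sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  idx <- match(colnames(em$values), annotations$sample_id)
  em$annotations <- annotations[idx, , drop = FALSE]
  rownames(em$annotations) <- NULL
  em
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (!is.null(x$annotations))
    cat("annotations:", paste(setdiff(names(x$annotations), "sample_id"),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Gene and sample identifiers of an expression matrix
#' @param em an [expr_matrix()].
#' @return character vector of identifiers, in matrix order.
#' @export
gene_ids <- function(em) rownames(em$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(em) colnames(em$values)

## Pull a per-sample annotation column, failing loudly if absent.
annotation_column <- function(em, key) {
  if (is.null(em$annotations))
    stop("expression matrix carries no annotations", call. = FALSE)
  if (!key %in% names(em$annotations))
    stop("annotation key '", key, "' not found (have: ",
         paste(setdiff(names(em$annotations), "sample_id"), collapse = ", "),
         ")", call. = FALSE)
  stats::setNames(as.character(em$annotations[[key]]), sample_ids(em))
}
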