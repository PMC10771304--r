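#' Read a tab-separated expression matrix
#'
#' Expects the microarray-style layout: first column `gene_id`, header
#' row of sample identifiers, numeric body. Row and column order are
#' preserved exactly as in the file. Parse problems are reported with
#' coordinates; duplicate identifiers and missing or non-numeric cells
#' are errors, never silently repaired.
#'
#' @param path path to a UTF-8 TSV file.
#' @param scale the scale the stored values are on, `"log2"` (default)
#'   or `"linear"`.
#' @param annotations optional path to a sample annotation TSV (see
#'   [read_annotations()]) to attach.
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(path, scale = c("log2", "linear"),
                                   annotations = NULL) {
  scale <- match.arg(scale)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L)
    stop("'", path, "': expected a gene_id column plus >=1 sample column",
         call. = FALSE)
  gid <- raw[[1L]]
  dup <- unique(gid[duplicated(gid)])
  if (length(dup))
    stop("'", path, "': duplicate gene id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  sid <- colnames(raw)[-1L]
  dup_s <- unique(sid[duplicated(sid)])
  if (length(dup_s))
    stop("'", path, "': duplicate sample id(s): ",
         paste(dup_s, collapse = ", "), call. = FALSE)
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf(
      "'%s': non-numeric or missing value '%s' at data row %d (gene '%s'), column %d (sample '%s')",
      path, body[i, j], i, gid[i], j, sid[j]), call. = FALSE)
  }
  dimnames(num) <- list(gid, sid)
  ann <- if (!is.null(annotations)) read_annotations(annotations) else NULL
  expr_matrix(num, scale = scale, annotations = ann)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: first column `gene_id`, sample
#' ids as header. Values are written with 15 significant digits so a
#' write/read round trip preserves them to well below 1e-9.
#'
#' @param em an [expr_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path) {
  stopifnot(inherits(em, "expr_matrix"))
  df <- data.frame(gene_id = gene_ids(em),
                   signif(em$values, 15),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' TSV with a mandatory `sample_id` column; remaining columns are
#' free-form per-sample keys such as `group` or `stratum`.
#'
#' @param path path to a TSV file.
#' @return A `data.frame`.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!"sample_id" %in% names(ann))
    stop("'", path, "': annotation table lacks a 'sample_id' column",
         call. = FALSE)
  if (anyDuplicated(ann$sample_id))
    stop("'", path, "': duplicate sample_id in annotations", call. = FALSE)
  ann
}

#' Write a result table as TSV
#'
#' Shared writer for all tabular results (DEG tables, score tables,
#' association tables, qPCR tables). Floating-point columns are rendered
#' with 6 significant digits; row order is the input order.
#'
#' @param records a `data.frame` with a fixed column schema.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a result table written by [write_table()]
#'
#' @param path path to a TSV file.
#' @return A `data.frame` with `check.names = FALSE`.
#' @export
read_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    quote = "", comment.char = "", stringsAsFactors = FALSE)
}
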