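#' Gene set with optional direction weights
#'
#' A named, ordered collection of unique gene identifiers with per-gene
#' weights in {+1, -1}. Weight +1 marks genes expected to move with the
#' signature, -1 against it; published repair and "BRCAness" lists carry
#' no directions, so +1 is the default throughout.
#'
#' @param name set name.
#' @param genes character vector of gene identifiers, unique.
#' @param weights numeric vector of +1/-1, recycled scalar allowed.
#' @param source free-text provenance.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, genes, weights = 1, source = "") {
  if (!length(genes)) stop("gene set '", name, "' is empty", call. = FALSE)
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    stop("gene set '", name, "' has duplicate genes", call. = FALSE)
  weights <- rep_len(as.numeric(weights), length(genes))
  if (!all(weights %in% c(-1, 1)))
    stop("weights must be +1 or -1", call. = FALSE)
  structure(list(name = as.character(name), genes = genes,
                 weights = weights, source = as.character(source)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes (%d negative-weight)\n",
              x$name, length(x$genes), sum(x$weights < 0)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' MSigDB dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene...`. The suffix convention `gene|-1`
#' encodes a negative weight. Duplicate genes within a line are
#' collapsed to their first occurrence with a warning; a line with fewer
#' than three fields is a parse error reported with its line number.
#'
#' @param path path to a GMT file.
#' @return A named list of [gene_set()] objects (possibly empty).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sets <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[[i]]))) next
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("'", path, "' line ", i, ": GMT line has fewer than 3 fields",
           call. = FALSE)
    name <- fields[[1L]]
    toks <- fields[-(1:2)]
    toks <- toks[nzchar(toks)]
    neg <- grepl("\\|-1$", toks)
    genes <- sub("\\|-1$", "", toks)
    genes <- sub("\\|1$", "", genes)
    keep <- !duplicated(genes)
    if (any(!keep))
      warning("'", path, "' line ", i, " (set '", name,
              "'): duplicate gene(s) collapsed: ",
              paste(unique(genes[!keep]), collapse = ", "), call. = FALSE)
    sets[[name]] <- gene_set(name, genes[keep],
                             ifelse(neg[keep], -1, 1),
                             source = fields[[2L]])
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param genesets a list of [gene_set()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(genesets, path) {
  lines <- vapply(genesets, function(gs) {
    toks <- ifelse(gs$weights < 0, paste0(gs$genes, "|-1"), gs$genes)
    paste(c(gs$name, if (nzchar(gs$source)) gs$source else "na", toks),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
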