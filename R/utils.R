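# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## All distinct two-group label assignments that preserve group sizes:
## a matrix with one column per assignment, rows indexing the samples
## that fall in the first group.
enumerate_assignments <- function(n, n_a) {
  utils::combn(n, n_a)
}

n_assignments <- function(n, n_a) choose(n, n_a)

## Nearest-rank percentile: the smallest element with cumulative
## proportion >= prob. Distribution-free and platform-stable, unlike
## interpolating quantile types.
nearest_rank <- function(x, prob) {
  stopifnot(length(x) > 0, prob > 0, prob <= 1)
  sort(x)[ceiling(prob * length(x))]
}

clip_pvalue <- function(p, floor = 1e-15) {
  pmin(pmax(p, floor), 1 - floor)
}

## Resolve a two-level group factor into a (treated, control) pair of
## labels. An explicit `treated` wins; otherwise "treated" is recognised
## by name; otherwise the first label in sorted order is taken as treated.
resolve_groups <- function(labels, treated = NULL) {
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2L)
    stop("expected exactly two groups, got: ", paste(lev, collapse = ", "),
         call. = FALSE)
  if (is.null(treated))
    treated <- if ("treated" %in% lev) "treated" else lev[[1L]]
  if (!treated %in% lev)
    stop("treated label '", treated, "' not present in groups", call. = FALSE)
  c(treated = treated, control = setdiff(lev, treated))
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == as.integer(x)
}

log_msg <- function(..., level = "INFO") {
  message(sprintf("[%s] %s", level, paste0(...)))
}
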