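# Independent brute-force oracles, kept deliberately separate from the
# package's code paths: everything here enumerates from first principles.

## Exact two-sided rank-sum p by enumerating all label assignments.
oracle_ranksum <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  mu <- na * (n + 1) / 2
  w_obs <- sum(r[seq_len(na)])
  idx <- combn(n, na)
  w_all <- apply(idx, 2, function(ia) sum(r[ia]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

## Exact median-difference permutation p by the same enumeration.
oracle_median_diff <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  t_obs <- median(a) - median(b)
  idx <- combn(n, na)
  t_all <- apply(idx, 2, function(ia)
    median(pooled[ia]) - median(pooled[-ia]))
  mean(abs(t_all) >= abs(t_obs) - 1e-12)
}

## Closed-form Stouffer combination, written out independently.
oracle_stouffer <- function(p, sgn) {
  z <- sum(sgn * qnorm(1 - p / 2)) / sqrt(3)
  list(z = z, p = 2 * (1 - pnorm(abs(z))))
}

## Small TSV fixture written in code.
write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

small_matrix_fixture <- function() {
  write_tsv_fixture(c(
    "gene_id\ts1\ts2\ts3\ts4",
    "CHEK1\t1.5\t2.5\t3.5\t4.5",
    "BRCA1\t2\t2\t2\t2",
    "RAD51\t0.1\t-0.2\t0.3\t-0.4"))
}
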