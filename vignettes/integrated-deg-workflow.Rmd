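---
title: "Integrated DEG calling, signature scoring and driver association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated DEG calling, signature scoring and driver association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degsig)
```

## The problem

Oxysterol signalling experiments in prostate cancer cell lines — for
example treating cells with 27-hydroxycholesterol, the product of the
sterol 27-hydroxylase encoded by *CYP27A1* — typically produce tiny
two-condition expression designs: three treated and three control
arrays per cell line. At n = 3 per group, no single test is
trustworthy: the t-test leans on a variance estimated from two degrees
of freedom per group, and rank tests are so discrete that their
smallest attainable p-value is 0.1. This package implements the
integrated strategy used for such designs, together with the
downstream machinery that connects a differential-expression result to
patient cohorts: signature scoring, stratified driver–signature
correlation, and qPCR validation statistics.

Everything is exercisable without any external download through a
synthetic-data module with *planted* structure, so each estimator can
be tested against a known truth.

## The integrated DEG caller

For each gene, three two-sided p-values are computed between the
treated and control samples:

* a pooled-variance Student t-test (`t_test_pvalue`); Welch's form is
  available behind a flag, but with three samples per group there is
  no information to stabilize separate variances, and the pooled form
  is the convention of this family of pipelines;
* a Wilcoxon rank-sum test (`ranksum_pvalue`), exact by full
  enumeration of all `choose(na+nb, na)` label assignments when that
  count is at most 10,000 and the data are tie-free, and a
  tie-corrected, continuity-corrected normal approximation otherwise;
* a median-difference permutation test (`median_diff_pvalue`) on
  `T = median(treated) − median(control)`, exhaustive over label
  assignments under the same 10,000 cap, Monte-Carlo with the add-one
  correction `(hits + 1)/(N + 1)` beyond it.

The three are combined by Stouffer's method (`stouffer_combine`):
each p is mapped to a normal score `z_i = s · Φ⁻¹(1 − p_i/2)` carrying
one **common** direction `s`, the sign of the observed median
difference, and `z_comb = Σ z_i / √3`, `p_comb = 2(1 − Φ(|z_comb|))`.
A single common sign is used because all three tests address the same
contrast; per-test signs would cancel haphazardly in borderline genes.
P-values are clipped to `[1e-15, 1 − 1e-15]` before the quantile
transform; the floor only matters for p-values far below anything the
rank tests can produce, so ranks are unaffected.

Multiple testing is corrected with Storey q-values
(`storey_qvalues`). The null proportion π₀ is estimated by the
smoother method — `π₀(λ) = #{p > λ}/(m(1 − λ))` on the grid
λ = 0.05, …, 0.95, smoothed by a natural cubic spline with 3 df and
read off at λ = 0.95, clipped to (0, 1]. Below 100 p-values the tail
histogram is too sparse to estimate π₀ and the implementation falls
back to π₀ = 1, where the q-values coincide exactly with
Benjamini–Hochberg adjusted p-values (a relation the tests assert on
random inputs).

A gene is called a DEG when **both**

1. its q-value is below `fdr_cut` (default 0.05), and
2. its absolute log2-median-ratio exceeds the 95th percentile
   (nearest-rank) of a permutation null pooled across genes ×
   permutations (`permutation_null_lmr`).

The null uses all distinct label assignments when there are at most
`n_perm` of them — a 3-vs-3 design has exactly 20, so a budget of
1,000 redundant random draws collapses to exhaustive enumeration —
and `n_perm` seeded draws otherwise, always including the identity
assignment as the conservative convention. The pooled (genome-wide)
null matches the notion of a single null distribution of the
log2-median-ratio; a per-gene threshold variant is deliberately out
of scope.

### Two structural caveats the tests make explicit

Both are consequences of design choices stated above, and both are
measured (not hidden) by the test suite:

**The combined p-value is not calibrated at n = 3.** Summing three
*absolute* normal scores under a common sign is anti-conservative even
for independent tests (the analytical type-I rate at the nominal 0.05
level is ≈ 0.17), and the three tests run on the same six values, so
they are strongly correlated. On 1,000 simulated null genes the
fraction with `p_comb < 0.05` is ≈ 0.19–0.23. The *caller* remains
near-silent under the null regardless — π₀-weighted q-values and the
permutation effect-size filter together yield zero to two false calls
per 1,000 null genes — but `p_comb` itself should be read as a ranking
score, not a calibrated tail probability.

**Three-sample medians are majority votes.** If a gene carries a
planted shift of Δ, then under *any* 3-vs-3 label reassignment each
pseudo-group median is dominated by its majority condition, so the
gene feeds values close to Δ into the permutation pool for most
assignments (mixed assignments contribute ≈ 0.72·Δ on average at
noise SD 0.25, identity and its complement the full Δ). With 10% of
genes planted at Δ = 1 the pooled 95th-percentile threshold rises to
≈ 0.75 rather than staying at the noise scale (≈ 0.45), and recall of
planted genes plateaus around 0.8–0.87 because a planted gene's own
observed |lmr| ~ N(1, 0.24) must clear a threshold of ≈ 0.75. The
same effect means the noise-free identity "planted gene ⇒ called"
holds only while planted genes make up less than 5% of the pooled
null. With the ~20,000-gene matrices and smaller strong-DE fractions
of real microarray data the contamination is far weaker; at the
1,000-gene, 10%-planted synthetic scale it is the binding constraint
on recall, and the acceptance suite reports it honestly.

## Weighted Z-score signature scoring

`median_center_scale` standardizes each gene across samples
(subtract the across-sample median, divide by the across-sample SD;
SD rather than MAD because the method is a Z-score — the median enters
only as the centering location). Zero-variance genes are dropped with
a warning. For a gene set with direction weights `w_i ∈ {+1, −1}`
(all published repair/"BRCAness" lists used here are undirected, so
+1 throughout), the per-sample score is

    score_j = Σ_i w_i z_ij / √(Σ_i w_i²)

so k concordant genes at a common standardized level z give a score
z·√k. Scores are invariant to per-gene affine transforms of the raw
data; a signature with no matched genes is *skipped*, never reported
as zero. `signature_group_test` compares scores between conditions
with a pooled-variance t-test, reporting the treated-minus-control
mean difference — the downregulation comparison for a repair program
under oxysterol treatment.

## Stratified driver–signature association

`spearman` computes rho as the Pearson correlation of mid-ranks
(tie-safe). The two-tailed p is exact by enumeration of all n! rank
permutations for n ≤ 9 tie-free observations, and uses the
t-approximation `t = ρ√((n−2)/(1−ρ²))` on n−2 df otherwise — cohort
analyses run at n in the hundreds, where the two are
indistinguishable. `correlate_driver_with_signatures` evaluates, per
stratum (Gleason-like groups, disease course) plus a pooled `"all"`
stratum, the correlation between a driver gene's expression and each
signature score. Driver expression is read from the same standardized
matrix used for scoring; standardization is monotone per gene, so
Spearman statistics are unchanged. Strata under 10 samples are
reported as skipped: below that, the t-approximation is unreliable
and real cohorts are far larger anyway.

## ΔΔCt statistics

`delta_delta_ct` averages technical replicates on the Ct scale
(standard practice; averaging after exponentiation would weight
replicates unevenly), forms per-sample
`ΔCt = Ct_target − Ct_housekeeping` (two housekeeping genes are
averaged per sample when both are supplied), and reports
`fold = 2^−ΔΔCt` with per-sample relative levels anchored so the
control group's mean is exactly 1. The group test is a pooled t-test
on the per-sample ΔCt values — equivalently log2 relative levels —
because variance is homogeneous on the log scale, not on the
exponentiated fold scale.

## What the synthetic generators emulate

* `generate_de_experiment`: a triplicate treated/control design with
  additive Gaussian noise on the log2 scale (the standard model for
  normalized arrays, and the choice that makes planted log2 effects
  exact). Planted genes shift by ±`effect_log2` with alternating
  signs. Defaults — 1,000 genes, 3 vs 3, 100 planted at |Δ| = 1,
  noise SD 0.25 — represent a clean 27HC-like cell-line experiment.
* `generate_cohort`: a Gaussian copula in which the driver and a
  k-gene signature block share a latent factor. Loadings are solved so
  the **population Spearman correlation between the driver and the
  signature-block mean equals the planted ρ** (using
  `r = 2 sin(πρ/6)` to convert the Spearman target into a latent
  Pearson correlation). The planted quantity is placed at the block
  level, because the reported statistic of interest is signature score
  vs driver expression; planting ρ per gene instead would make the
  de-noised block score correlate *more* strongly than ρ (≈ 0.66 for
  a per-gene 0.5 at k = 10), i.e. the generator would not recover its
  own truth parameter. Per-gene correlations are therefore mildly
  attenuated below ρ.
* `generate_qpcr`: triplicate technical replicates of one target and
  one housekeeping gene, a per-sample loading offset common to both
  genes (which ΔCt must cancel), and a treated-group target shift of
  `−log2(fold)` cycles.

None of the generators model probe effects, batch structure,
background correction, count noise, or single-cell sparsity; passing
tests demonstrate correctness of the statistical machinery under its
own model, not robustness to real-array artefacts.

## Numerical and policy choices

* Exhaustive-vs-approximate switches for the permutation tests sit at
  10,000 assignments; exhaustive p-values use the plain proportion,
  Monte-Carlo p-values the add-one correction.
* Percentiles are nearest-rank (sorted value at `ceiling(0.95 N)`):
  distribution-free and identical across platforms, unlike
  interpolating quantile types.
* Tie comparisons in permutation tests use a 1e-12 slack so that
  floating-point noise cannot demote an exactly-tied statistic.
* Gene identifiers are opaque, case-sensitive strings; matrix
  orientation is fixed genes-in-rows; missing values are parse errors.
* All stochastic stages take explicit seeds; the pipeline writes a
  manifest with MD5 hashes so reruns can be verified byte-identical.

## Problem sizes used by the test and acceptance suites

The simulations run at 1,000 genes (DEG calling, calibration), 100
replicates of 200-gene experiments (signature detection), cohorts of
n = 300 (association), and n = 3 per group for qPCR — sizes chosen to
match the designs being emulated while keeping each check's Monte-Carlo
error well below the tolerance it asserts.

## A worked run

```{r example, eval = FALSE}
cfg <- list(
  seed = 11L, out_dir = "demo_run",
  simulate = list(
    experiment = list(n_genes = 500, n_de = 25, effect_log2 = 1,
                      noise_sd = 0.25),
    cohort = list(n_patients = 300, driver_rho = -0.5,
                  strata = list(cspc = 150, mcrpc = 150)),
    qpcr = list(planted_fold = 0.5, ct_sd = 0.2)),
  deg = list(fdr_cut = 0.05, n_perm = 1000),
  score = list(), correlate = list(), qpcr = list())
res <- run_pipeline(cfg)
read_table(file.path(res$out_dir, "associations.tsv"))
```
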