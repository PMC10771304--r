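#' Specification of a planted two-condition experiment
#'
#' Describes a synthetic treated-vs-control expression experiment on the
#' log2 scale: `n_de` of `n_genes` genes carry a planted mean shift of
#' `effect_log2` (signs alternating + / - across planted genes), every
#' entry gets iid Gaussian noise. The defaults mirror a triplicate
#' treatment design (3 vs 3), the setting the integrated DEG caller is
#' aimed at.
#'
#' @param n_genes total number of genes.
#' @param n_per_group samples per condition (>= 2).
#' @param n_de number of planted differentially expressed genes.
#' @param effect_log2 planted mean shift, log2 units.
#' @param noise_sd residual standard deviation, log2 units (> 0).
#' @param seed integer seed; every generated artifact is a deterministic
#'   function of the spec including its seed.
#' @return An object of class `de_plant_spec`.
#' @export
de_plant_spec <- function(n_genes = 1000, n_per_group = 3, n_de = 100,
                          effect_log2 = 1, noise_sd = 0.25, seed = 1) {
  stopifnot(is_count(n_genes, 1), is_count(n_de, 0), is_count(seed))
  if (n_de > n_genes) stop("n_de must be <= n_genes", call. = FALSE)
  if (!is_count(n_per_group, 2))
    stop("n_per_group must be an integer >= 2", call. = FALSE)
  if (!(is.numeric(noise_sd) && noise_sd > 0))
    stop("noise_sd must be > 0", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 n_de = as.integer(n_de), effect_log2 = effect_log2,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "de_plant_spec")
}

#' Generate a planted two-condition expression experiment
#'
#' Produces a log2-scale [expr_matrix()] with `2 * n_per_group` samples
#' annotated `group` in treated/control, plus a per-gene truth table.
#' Entry model: `baseline_g + shift_g * treated + N(0, noise_sd^2)`
#' with gene baselines drawn once from N(7, 1). The planted genes are
#' the first `n_de` rows; their shifts alternate `+effect_log2`,
#' `-effect_log2`.
#'
#' @param spec a [de_plant_spec()].
#' @return A list with elements `matrix` (the [expr_matrix()]) and
#'   `truth` (`data.frame` of `gene_id`, `is_de`, `effect_log2`).
#' @examples
#' sim <- generate_de_experiment(de_plant_spec(n_genes = 50, n_de = 5))
#' table(sim$truth$is_de)
#' @export
generate_de_experiment <- function(spec) {
  stopifnot(inherits(spec, "de_plant_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes; npg <- spec$n_per_group; n <- 2L * npg
  gid <- sprintf("G%05d", seq_len(ng))
  sid <- c(sprintf("T%02d", seq_len(npg)), sprintf("C%02d", seq_len(npg)))
  group <- rep(c("treated", "control"), each = npg)
  baseline <- stats::rnorm(ng, mean = 7, sd = 1)
  values <- baseline + matrix(stats::rnorm(ng * n, 0, spec$noise_sd), ng, n)
  effect <- numeric(ng)
  if (spec$n_de > 0)
    effect[seq_len(spec$n_de)] <-
      rep_len(c(1, -1), spec$n_de) * spec$effect_log2
  values[, group == "treated"] <- values[, group == "treated"] + effect
  dimnames(values) <- list(gid, sid)
  ann <- data.frame(sample_id = sid, group = group,
                    stringsAsFactors = FALSE)
  list(matrix = expr_matrix(values, scale = "log2", annotations = ann),
       truth = data.frame(gene_id = gid, is_de = effect != 0,
                          effect_log2 = effect, stringsAsFactors = FALSE))
}

#' Specification of a planted patient cohort
#'
#' Describes a synthetic cohort in which one designated driver gene and
#' a block of signature genes share a latent Gaussian factor, so the
#' population Spearman correlation between the driver and the signature
#' block is a planted value. Strata (e.g. Gleason-like groups or disease
#' course) are generated independently, each with its own sample size
#' and planted correlation.
#'
#' @param n_patients total patients when `strata` is `NULL`; otherwise
#'   derived from the per-stratum sizes.
#' @param n_signature_genes genes in the correlated signature block.
#' @param driver_rho planted Spearman correlation between driver
#'   expression and the signature block, in (-1, 1); a scalar, or one
#'   value per stratum.
#' @param strata named integer vector of per-stratum sample sizes
#'   (each >= 10), or `NULL` for a single stratum `"all"`.
#' @param noise_sd per-gene residual SD relative to the unit-variance
#'   latent factor; controls how noisy individual signature genes are
#'   around the shared factor.
#' @param n_background additional uncorrelated genes, so standardization
#'   and scoring run against a realistic background.
#' @param seed integer seed.
#' @return An object of class `cohort_plant_spec`.
#' @export
cohort_plant_spec <- function(n_patients = 300, n_signature_genes = 10,
                              driver_rho = -0.5, strata = NULL,
                              noise_sd = 0.5, n_background = 50, seed = 1) {
  if (is.null(strata))
    strata <- stats::setNames(as.integer(n_patients), "all")
  if (is.null(names(strata)) || any(!nzchar(names(strata))))
    stop("strata must be a named vector of sizes", call. = FALSE)
  if (any(strata < 10))
    stop("each stratum needs n >= 10", call. = FALSE)
  rho <- rep_len(as.numeric(driver_rho), length(strata))
  if (any(rho <= -1 | rho >= 1))
    stop("driver_rho must lie in (-1, 1)", call. = FALSE)
  stopifnot(is_count(n_signature_genes, 1), is_count(n_background, 0),
            is_count(seed), is.numeric(noise_sd), noise_sd > 0)
  structure(list(strata = stats::setNames(as.integer(strata), names(strata)),
                 n_signature_genes = as.integer(n_signature_genes),
                 driver_rho = stats::setNames(rho, names(strata)),
                 noise_sd = noise_sd,
                 n_background = as.integer(n_background),
                 seed = as.integer(seed)),
            class = "cohort_plant_spec")
}

## Loadings of the bivariate-normal copula behind generate_cohort.
## Target: population Spearman(driver, mean of k signature genes) = rho.
## For bivariate normals Spearman rho_s = (6/pi) asin(r/2), so the
## latent Pearson correlation to hit is r = 2 sin(pi rho_s / 6). With
## gene_i = b f + sqrt(1-b^2) e_i and score = mean(gene_i), the
## driver loading a must satisfy a * b / sqrt(b^2 + (1-b^2)/k) = r.
cohort_loadings <- function(rho, noise_sd, k) {
  r <- 2 * sin(pi * rho / 6)
  b <- 1 / sqrt(1 + noise_sd^2)
  a <- r * sqrt(b^2 + (1 - b^2) / k) / b
  if (abs(a) >= 1)
    stop("driver_rho ", rho, " not attainable at noise_sd ", noise_sd,
         " with ", k, " signature genes", call. = FALSE)
  list(a = a, b = b)
}

#' Generate a cohort with a planted driver-signature association
#'
#' Builds, per stratum, a latent factor `f ~ N(0,1)`; the driver gene is
#' `a f + sqrt(1-a^2) e` and each signature gene `b f + sqrt(1-b^2) e_i`
#' (a Gaussian copula), with loadings chosen so the population Spearman
#' correlation between driver expression and the signature-block mean
#' equals the planted `driver_rho` of that stratum. Individual
#' driver-gene correlations are then slightly attenuated below
#' `driver_rho`, since averaging the block removes gene-level noise.
#' Values are shifted to a log2-expression-like location (monotone, so
#' rank statistics are unaffected). Background genes are iid noise.
#'
#' @param spec a [cohort_plant_spec()].
#' @return A list: `matrix` (an [expr_matrix()] with `group` = stratum in
#'   its annotations under key `stratum`), `driver_gene` (its id),
#'   `signature` (a [gene_set()] over the planted block), and
#'   `planted_rho` (named per-stratum vector).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_plant_spec"))
  set.seed(spec$seed)
  k <- spec$n_signature_genes
  driver_id <- "DRIVER1"
  sig_ids <- sprintf("SIG%03d", seq_len(k))
  bg_ids <- if (spec$n_background > 0)
    sprintf("BG%03d", seq_len(spec$n_background)) else character(0)
  blocks <- vector("list", length(spec$strata))
  sid_all <- character(0); stratum_all <- character(0)
  for (s in seq_along(spec$strata)) {
    n <- spec$strata[[s]]
    ld <- cohort_loadings(spec$driver_rho[[s]], spec$noise_sd, k)
    f <- stats::rnorm(n)
    driver <- ld$a * f + sqrt(1 - ld$a^2) * stats::rnorm(n)
    sig <- vapply(seq_len(k), function(i)
      ld$b * f + sqrt(1 - ld$b^2) * stats::rnorm(n), numeric(n))
    bg <- if (spec$n_background > 0)
      matrix(stats::rnorm(n * spec$n_background), n) else
      matrix(numeric(0), n, 0)
    blocks[[s]] <- cbind(driver, sig, bg)
    sid_all <- c(sid_all, sprintf("P_%s_%03d", names(spec$strata)[s],
                                  seq_len(n)))
    stratum_all <- c(stratum_all, rep(names(spec$strata)[s], n))
  }
  values <- t(do.call(rbind, blocks)) + 7  # genes x patients, log2-like
  dimnames(values) <- list(c(driver_id, sig_ids, bg_ids), sid_all)
  ann <- data.frame(sample_id = sid_all, stratum = stratum_all,
                    stringsAsFactors = FALSE)
  list(matrix = expr_matrix(values, scale = "log2", annotations = ann),
       driver_gene = driver_id,
       signature = gene_set("PLANTED_SIGNATURE", sig_ids,
                            source = "synthetic planted block"),
       planted_rho = spec$driver_rho)
}

#' Generate a synthetic qPCR Ct table
#'
#' One target and one housekeeping gene measured in technical triplicate
#' per sample. The target's treated-group Ct is offset by
#' `-log2(planted_fold)` relative to control (one extra cycle per
#' halving of expression); the housekeeping gene is independent of
#' group. A per-sample loading offset shifts both genes of a sample
#' equally, which the delta-Ct normalization must cancel.
#'
#' @param n_per_group samples per group.
#' @param planted_fold true treated/control expression fold change (> 0).
#' @param ct_sd technical replicate SD on the Ct scale.
#' @param seed integer seed.
#' @param n_replicates technical replicates per (sample, gene).
#' @param target,housekeeping gene identifiers used in the table.
#' @param loading_sd SD of the shared per-sample Ct offset.
#' @return A long-format `data.frame` with columns `sample_id`, `group`,
#'   `gene_id`, `role`, `replicate`, `ct`.
#' @export
generate_qpcr <- function(n_per_group = 3, planted_fold = 0.5, ct_sd = 0.2,
                          seed = 1, n_replicates = 3, target = "TARGET1",
                          housekeeping = "GAPDH", loading_sd = 0.3) {
  if (!(is.numeric(planted_fold) && planted_fold > 0))
    stop("planted_fold must be > 0", call. = FALSE)
  stopifnot(is_count(n_per_group, 2), is_count(n_replicates, 1),
            is_count(seed), ct_sd >= 0, loading_sd >= 0)
  set.seed(seed)
  sid <- c(sprintf("T%02d", seq_len(n_per_group)),
           sprintf("C%02d", seq_len(n_per_group)))
  group <- rep(c("treated", "control"), each = n_per_group)
  loading <- stats::rnorm(length(sid), 0, loading_sd)
  rows <- list()
  for (i in seq_along(sid)) {
    ## treated target Ct shifts by -log2(fold): fold 0.5 => +1 cycle
    tgt_mu <- 25 + loading[i] +
      if (group[i] == "treated") -log2(planted_fold) else 0
    hk_mu <- 18 + loading[i]
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sid[i], group = group[i], gene_id = target,
      role = "target", replicate = seq_len(n_replicates),
      ct = tgt_mu + stats::rnorm(n_replicates, 0, ct_sd),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sid[i], group = group[i], gene_id = housekeeping,
      role = "housekeeping", replicate = seq_len(n_replicates),
      ct = hk_mu + stats::rnorm(n_replicates, 0, ct_sd),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
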