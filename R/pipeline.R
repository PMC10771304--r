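#' Validate a pipeline run configuration
#'
#' The configuration is a flat, diff-friendly key-value document (YAML
#' on disk, a named list in R). Top-level keys: `seed` (mandatory),
#' `out_dir`, and one block per stage to run — `simulate`, `deg`,
#' `score`, `correlate`, `qpcr`. Stage blocks name their input paths
#' (defaulting to the artifacts of earlier stages) and parameters
#' (`fdr_cut` in (0,1), `n_perm` >= 100, `group_key`, `driver_gene`,
#' `stratum_key`, ...). Validation happens up front, before any stage
#' runs.
#'
#' @param config named list, or path to a YAML file.
#' @return The validated config list (class `run_config`).
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  if (!is_count(config$seed %||% NA))
    stop("config requires an integer 'seed'", call. = FALSE)
  config$out_dir <- config$out_dir %||% "degsig_run"
  if (!is.null(config$deg)) {
    fdr <- config$deg$fdr_cut %||% 0.05
    if (!(is.numeric(fdr) && fdr > 0 && fdr < 1))
      stop("deg.fdr_cut must lie in (0, 1)", call. = FALSE)
    np <- config$deg$n_perm %||% 1000
    if (!is_count(np, 100))
      stop("deg.n_perm must be an integer >= 100", call. = FALSE)
    config$deg$fdr_cut <- fdr; config$deg$n_perm <- np
  }
  structure(config, class = c("run_config", "list"))
}

#' Write synthetic inputs for a pipeline run
#'
#' Materializes the synthetic bundle a full run consumes: a planted
#' two-condition experiment (matrix + annotations + per-gene truth), a
#' planted cohort (matrix + stratum annotations + signature GMT +
#' planted correlations), and a planted qPCR Ct table — all in the same
#' TSV/GMT formats the readers accept, all deterministic functions of
#' the configured parameters and seed.
#'
#' @param config a [read_run_config()] list with a `simulate` block;
#'   sub-blocks `experiment`, `cohort`, `qpcr` override
#'   [de_plant_spec()], [cohort_plant_spec()] and [generate_qpcr()]
#'   defaults.
#' @param out_dir output directory (created if needed).
#' @return Named character vector of written file paths.
#' @export
simulate_inputs <- function(config, out_dir = config$out_dir) {
  config <- read_run_config(config)
  sim <- config$simulate %||% list()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  paths <- c()
  p <- function(f) file.path(out_dir, f)

  ex_args <- utils::modifyList(list(seed = seed), sim$experiment %||% list())
  ex <- generate_de_experiment(do.call(de_plant_spec, ex_args))
  write_expression_matrix(ex$matrix, p("experiment.tsv"))
  write_table(ex$matrix$annotations, p("experiment_annotations.tsv"))
  write_table(ex$truth, p("truth_genes.tsv"))

  co_args <- utils::modifyList(list(seed = seed + 1L), sim$cohort %||% list())
  if (!is.null(co_args$strata)) co_args$strata <- unlist(co_args$strata)
  co <- generate_cohort(do.call(cohort_plant_spec, co_args))
  write_expression_matrix(co$matrix, p("cohort.tsv"))
  write_table(co$matrix$annotations, p("cohort_annotations.tsv"))
  write_gmt(list(co$signature), p("signatures.gmt"))
  write_table(data.frame(stratum = names(co$planted_rho),
                         planted_rho = as.numeric(co$planted_rho),
                         driver_gene = co$driver_gene,
                         stringsAsFactors = FALSE),
              p("truth_cohort.tsv"))

  qp_args <- utils::modifyList(list(seed = seed + 2L), sim$qpcr %||% list())
  write_table(do.call(generate_qpcr, qp_args), p("qpcr.tsv"))

  log_msg("simulate: wrote synthetic bundle to ", out_dir,
          " (seed ", seed, ")")
  c(experiment = p("experiment.tsv"),
    experiment_annotations = p("experiment_annotations.tsv"),
    truth_genes = p("truth_genes.tsv"),
    cohort = p("cohort.tsv"),
    cohort_annotations = p("cohort_annotations.tsv"),
    signatures = p("signatures.gmt"),
    truth_cohort = p("truth_cohort.tsv"),
    qpcr = p("qpcr.tsv"))
}

#' Run the analysis pipeline end to end
#'
#' Executes the configured stages in order — `simulate` (optional),
#' `deg`, `score`, `correlate`, `qpcr` — writing every result table via
#' [write_table()] plus a manifest (`manifest.tsv`) listing each
#' artifact with its MD5 hash and the run seed. Identical configuration
#' and inputs produce byte-identical outputs. A stage failure aborts
#' with a nonzero status; the manifest written so far marks the
#' completed stages.
#'
#' @param config named list or YAML path, see [read_run_config()].
#' @return Invisibly, a list with `status` (0 on success), `manifest`
#'   (`data.frame`), and `out_dir`.
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  manifest <- data.frame(stage = character(0), artifact = character(0),
                         md5 = character(0), stringsAsFactors = FALSE)
  note <- function(stage, paths) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, artifact = basename(unname(paths)),
      md5 = unname(tools::md5sum(unname(paths))),
      stringsAsFactors = FALSE))
    write_table(cbind(manifest, seed = seed),
                file.path(out_dir, "manifest.tsv"))
  }

  sim_paths <- NULL
  if (!is.null(config$simulate)) {
    sim_paths <- simulate_inputs(config, out_dir)
    note("simulate", sim_paths)
  }

  if (!is.null(config$deg)) {
    cfg <- config$deg
    mat_path <- cfg$matrix %||% sim_paths[["experiment"]]
    ann_path <- cfg$annotations %||% sim_paths[["experiment_annotations"]]
    em <- read_expression_matrix(mat_path, scale = cfg$scale %||% "log2",
                                 annotations = ann_path)
    labels <- annotation_column(em, cfg$group_key %||% "group")
    res <- run_integrated_deg(em, labels = labels, fdr_cut = cfg$fdr_cut,
                              n_perm = cfg$n_perm, seed = seed)
    write_table(res$deg, file.path(out_dir, "deg_table.tsv"))
    write_table(data.frame(threshold = res$null$threshold,
                           n_perm = res$null$n_perm,
                           exhaustive = res$null$exhaustive,
                           pooled_size = length(res$null$pooled_abs_lmr)),
                file.path(out_dir, "lmr_null.tsv"))
    note("deg", c(file.path(out_dir, "deg_table.tsv"),
                  file.path(out_dir, "lmr_null.tsv")))
  }

  scores_path <- NULL
  if (!is.null(config$score)) {
    cfg <- config$score
    mat_path <- cfg$matrix %||% sim_paths[["cohort"]]
    ann_path <- cfg$annotations %||% sim_paths[["cohort_annotations"]]
    em <- read_expression_matrix(mat_path, scale = cfg$scale %||% "log2",
                                 annotations = ann_path)
    sets <- read_gmt(cfg$gmt %||% sim_paths[["signatures"]])
    scores <- score_signatures(em, sets)
    scores_path <- file.path(out_dir, "signature_scores.tsv")
    write_table(scores, scores_path)
    note("score", scores_path)
  }

  if (!is.null(config$correlate)) {
    cfg <- config$correlate
    mat_path <- cfg$matrix %||% sim_paths[["cohort"]]
    ann_path <- cfg$annotations %||% sim_paths[["cohort_annotations"]]
    em <- read_expression_matrix(mat_path, scale = cfg$scale %||% "log2",
                                 annotations = ann_path)
    scores <- read_table(cfg$scores %||% scores_path)
    driver <- cfg$driver_gene %||%
      read_table(sim_paths[["truth_cohort"]])$driver_gene[[1L]]
    assoc <- correlate_driver_with_signatures(
      em, driver, scores, stratum_key = cfg$stratum_key %||% "stratum",
      min_n = cfg$min_n %||% 10)
    write_table(assoc, file.path(out_dir, "associations.tsv"))
    note("correlate", file.path(out_dir, "associations.tsv"))
  }

  if (!is.null(config$qpcr)) {
    cfg <- config$qpcr
    tab <- read_table(cfg$table %||% sim_paths[["qpcr"]])
    res <- delta_delta_ct(tab, cfg$target %||% "TARGET1",
                          cfg$housekeeping %||% "GAPDH")
    write_table(cbind(res$per_sample, fold_change = res$fold_change,
                      ddct = res$ddct, group_p = res$group_p),
                file.path(out_dir, "qpcr_results.tsv"))
    note("qpcr", file.path(out_dir, "qpcr_results.tsv"))
  }

  log_msg("pipeline complete: ", nrow(manifest), " artifact(s) in ",
          out_dir)
  invisible(list(status = 0L, manifest = manifest, out_dir = out_dir))
}
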