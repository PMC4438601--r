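default_run_config <- function() {
  list(mode = "synthetic",
       outdir = "swnet-run",
       seed = 1L,
       cohort = list(),          # cohort_spec() overrides (synthetic mode)
       input = list(timeseries_dir = NULL, clinical = NULL,
                    nifti_dir = NULL, centers = NULL, radius_mm = 5,
                    tr = NULL),
       preprocess = list(enabled = FALSE, k_discard = 2L, low_hz = 0.009,
                         high_hz = 0.08, dvars_stage = "raw"),
       connectivity = list(method = "partial", shrinkage = "auto"),
       metrics = list(grid = seq(0.1, 0.5, by = 0.05), n_rand = 100L,
                      metrics = c("C", "Eglob", "Eloc", "Q", "sigma"),
                      n_restarts = 20L),
       stats = list(alpha = 0.05, m_global = 3L, predictor = "sigma"))
}

#' Read and validate a pipeline run configuration
#'
#' The configuration is a single YAML file mirroring
#' [run_pipeline()]'s sections (`mode`, `outdir`, `seed`, `cohort`,
#' `input`, `preprocess`, `connectivity`, `metrics`, `stats`); absent
#' keys take the documented defaults. Validation errors name the
#' offending field.
#'
#' @param path YAML file path, or a list already in memory.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list.
#' @export
validate_run_config <- function(cfg) {
  base <- default_run_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown))
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg <- modifyList(base, cfg)
  if (!cfg$mode %in% c("synthetic", "timeseries", "nifti"))
    stopf("config field `mode` must be 'synthetic', 'timeseries' or 'nifti'")
  cfg$seed <- check_count(cfg$seed, "seed", lower = 0L)
  g <- cfg$metrics$grid
  if (any(g <= 0 | g >= 1))
    stopf("config field `metrics.grid` must lie strictly inside (0, 1)")
  if (is.unsorted(g, strictly = TRUE))
    stopf("config field `metrics.grid` must be strictly increasing")
  cfg$metrics$n_rand <- check_count(cfg$metrics$n_rand, "metrics.n_rand",
                                    lower = 0L)
  if (!cfg$connectivity$method %in% c("partial", "pearson"))
    stopf("config field `connectivity.method` must be 'partial' or 'pearson'")
  if (cfg$mode == "timeseries") {
    if (is.null(cfg$input$timeseries_dir))
      stopf("config field `input.timeseries_dir` is required in timeseries mode")
    if (!dir.exists(cfg$input$timeseries_dir))
      stopf("input.timeseries_dir not found: %s", cfg$input$timeseries_dir)
    if (is.null(cfg$input$clinical) || !file.exists(cfg$input$clinical))
      stopf("config field `input.clinical` must name an existing CSV")
  }
  if (cfg$mode == "nifti") {
    if (is.null(cfg$input$nifti_dir) || !dir.exists(cfg$input$nifti_dir))
      stopf("config field `input.nifti_dir` must name an existing directory")
    if (is.null(cfg$input$centers) || !file.exists(cfg$input$centers))
      stopf("config field `input.centers` must name an existing coordinate CSV")
    if (is.null(cfg$input$clinical) || !file.exists(cfg$input$clinical))
      stopf("config field `input.clinical` must name an existing CSV")
  }
  class(cfg) <- "run_config"
  cfg
}

md5_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

stage_current <- function(manifest, stage, key, files) {
  st <- manifest$stages[[stage]]
  !is.null(st) && identical(st$key, key) && all(file.exists(files)) &&
    identical(unname(tools::md5sum(files)), unlist(st$checksums,
                                                   use.names = FALSE))
}

#' Run the end-to-end connectome pipeline
#'
#' Orchestrates simulate/load -> preprocess -> connectivity -> metrics
#' -> statistics from a single configuration, writing each stage's
#' outputs (CSV/TSV/JSON) plus a `manifest.json` recording the config,
#' seeds, per-stage config keys, output checksums and timings, and a
#' human-readable `report.md`. A rerun with an unchanged configuration
#' skips stages whose recorded outputs are intact (checksums match),
#' recomputing only downstream of any change; results are a pure
#' function of (config, seed).
#'
#' @param config a [read_run_config()] result, a path to a YAML config,
#'   or a plain list.
#' @param outdir,seed optional overrides of the config fields.
#' @return (invisibly) list with the stats-stage results and file paths.
#' @export
run_pipeline <- function(config = list(), outdir = NULL, seed = NULL) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (!is.null(seed)) cfg$seed <- check_count(seed, "seed", lower = 0L)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(cfg$outdir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list(stages = list())
  manifest$config <- unclass(cfg)
  manifest$config_hash <- md5_of(unclass(cfg))
  timings <- list()

  finish_stage <- function(stage, key, files) {
    manifest$stages[[stage]] <<- list(key = key,
                                      files = as.list(files),
                                      checksums =
                                        as.list(unname(tools::md5sum(files))))
  }

  ## stage 1: cohort (simulate or load) --------------------------------
  t0 <- Sys.time()
  cohort_dir <- file.path(cfg$outdir, "cohort")
  key1 <- md5_of(list(cfg$mode, cfg$cohort, cfg$input, cfg$seed))
  clinical_file <- file.path(cohort_dir, "clinical.csv")
  if (cfg$mode == "synthetic") {
    spec <- do.call(cohort_spec,
                    modifyList(list(seed = cfg$seed, effect_beta = 0),
                               cfg$cohort))
    cohort <- generate_cohort(spec)
    files1 <- c(vapply(cohort$timeseries, function(p)
      file.path(cohort_dir, sprintf("%s_pre.tsv", p$pre$subject_id)), ""),
      clinical_file)
    if (!stage_current(manifest, "cohort", key1, files1)) {
      write_cohort(cohort, cohort_dir)
      finish_stage("cohort", key1, files1)
    }
  } else {
    ext <- if (cfg$mode == "nifti") "\\.nii(\\.gz)?$" else "\\.tsv$"
    src_dir <- if (cfg$mode == "nifti") cfg$input$nifti_dir else
      cfg$input$timeseries_dir
    files <- list.files(src_dir, pattern = ext, full.names = TRUE)
    if (!length(files)) stopf("no scans matching %s in %s", ext, src_dir)
    base <- sub(ext, "", basename(files))
    ids <- sub("_(pre|post)$", "", base)
    sessions <- sub("^.*_(pre|post)$", "\\1", base)
    centers <- NULL
    if (cfg$mode == "nifti") {
      ctab <- read.csv(cfg$input$centers)
      centers <- as.matrix(ctab[, c("x", "y", "z")])
      if ("node_id" %in% names(ctab)) rownames(centers) <- ctab$node_id
    }
    cohort <- list(timeseries = lapply(unique(ids), function(id) {
      pair <- list()
      for (sess in c("pre", "post")) {
        f <- files[ids == id & sessions == sess]
        if (length(f) != 1L)
          stopf("subject %s: expected one %s scan, found %d", id, sess,
                length(f))
        ts <- if (cfg$mode == "nifti")
          extract_node_timeseries(f, centers,
                                  radius_mm = cfg$input$radius_mm,
                                  tr = cfg$input$tr)
        else read_timeseries(f)
        ts$subject_id <- id
        ts$session <- sess
        pair[[sess]] <- ts
      }
      pair
    }),
    clinical = read.csv(cfg$input$clinical))
    finish_stage("cohort", key1, c(files, cfg$input$clinical))
  }
  timings$cohort <- as.numeric(Sys.time() - t0, units = "secs")

  ## stage 2+3+4: preprocess, connectivity, metric AUCs ----------------
  t0 <- Sys.time()
  key2 <- md5_of(list(key1, cfg$preprocess, cfg$connectivity, cfg$metrics))
  auc_file <- file.path(cfg$outdir, "auc.csv")
  dvars_file <- file.path(cfg$outdir, "dvars.csv")
  if (!stage_current(manifest, "metrics", key2, c(auc_file, dvars_file))) {
    cm <- cohort_metrics(cohort, grid = cfg$metrics$grid,
                         n_rand = cfg$metrics$n_rand,
                         metrics = cfg$metrics$metrics,
                         method = cfg$connectivity$method,
                         shrinkage = cfg$connectivity$shrinkage,
                         seed = seed_stream(cfg$seed, 2L),
                         preprocess = isTRUE(cfg$preprocess$enabled),
                         k_discard = cfg$preprocess$k_discard,
                         n_restarts = cfg$metrics$n_restarts)
    write.csv(cm$auc, auc_file, row.names = FALSE)
    write.csv(cm$dvars, dvars_file, row.names = FALSE)
    finish_stage("metrics", key2, c(auc_file, dvars_file))
  }
  # downstream statistics always consume the on-disk stage output, so a
  # cached rerun is bit-identical to a fresh one
  cm <- list(auc = read.csv(auc_file), dvars = read.csv(dvars_file))
  class(cm$auc) <- c("auc_table", "data.frame")
  timings$metrics <- as.numeric(Sys.time() - t0, units = "secs")

  ## stage 5: statistics ------------------------------------------------
  t0 <- Sys.time()
  key3 <- md5_of(list(key2, cfg$stats))
  stats_file <- file.path(cfg$outdir, "stats.json")
  report_file <- file.path(cfg$outdir, "report.md")
  if (!stage_current(manifest, "stats", key3, c(stats_file, report_file))) {
    res <- pipeline_stats(cm$auc, cm$dvars, cohort$clinical, cfg)
    jsonlite::write_json(res, stats_file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    write_report(res, cfg, report_file)
    finish_stage("stats", key3, c(stats_file, report_file))
  } else {
    res <- jsonlite::read_json(stats_file)
  }
  timings$stats <- as.numeric(Sys.time() - t0, units = "secs")

  manifest$timings <- timings
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(list(stats = res, auc = cm$auc, dvars = cm$dvars,
                 clinical = cohort$clinical, outdir = cfg$outdir))
}

# Group statistics over the AUC table: motion residualization, paired
# pre/post change tests, change-change partial correlations, follow-up
# prediction, outcome classification.
pipeline_stats <- function(auc_tab, dvars, clinical, cfg) {
  alpha_global <- bonferroni_alpha(cfg$stats$alpha, cfg$stats$m_global)
  adj <- residualize_on_motion(auc_tab, dvars)
  mets <- unique(adj$metric)
  paired <- lapply(setNames(mets, mets), function(m) {
    d <- adj[adj$metric == m, ]
    pre <- d$auc[d$session == "pre"][order(d$subject_id[d$session == "pre"])]
    post <- d$auc[d$session == "post"][order(d$subject_id[d$session ==
                                                            "post"])]
    if (!all(is.finite(pre)) || !all(is.finite(post)))
      return(list(metric = m,
                  skipped = "non-finite AUC (degenerate graphs at this size)"))
    r <- paired_change_test(pre, post,
                            seed = seed_stream(cfg$seed, 31L, match(m, mets)))
    list(metric = m, method = r$method, statistic = r$statistic, p = r$p,
         mean_change = r$effect, alpha_corrected = as.numeric(alpha_global))
  })
  ## change-change partial correlations (mean pre/post DVARS as covariate)
  chg <- NULL
  if (!is.null(clinical) && all(c("ybocs_pre", "ybocs_post") %in%
                                names(clinical))) {
    ord <- order(clinical$subject_id)
    cl <- clinical[ord, ]
    dv_mean <- (cl$dvars_pre + cl$dvars_post) / 2
    y_chg <- cl$ybocs_post - cl$ybocs_pre
    chg <- lapply(setNames(mets, mets), function(m) {
      d <- adj[adj$metric == m, ]
      pre <- d$auc[d$session == "pre"][order(d$subject_id[d$session ==
                                                            "pre"])]
      post <- d$auc[d$session == "post"][order(d$subject_id[d$session ==
                                                              "post"])]
      if (!all(is.finite(pre)) || !all(is.finite(post)))
        return(list(metric = m, skipped = "non-finite AUC"))
      r <- partial_corr(post - pre, y_chg, cbind(dvars = dv_mean))
      list(metric = m, r = r$effect, p = r$p)
    })
  }
  ## follow-up prediction from pre-treatment AUC
  fup <- NULL
  if (!is.null(clinical) && "ybocs_followup" %in% names(clinical)) {
    ord <- order(clinical$subject_id)
    cl <- clinical[ord, ]
    m <- cfg$stats$predictor
    d <- adj[adj$metric == m & adj$session == "pre", ]
    pre <- d$auc[order(d$subject_id)]
    fup <- tryCatch({
      fit <- fit_followup_regression(cl, pre, predictor_name = m)
      list(predictor = m, coefficient = fit$coefficients[["auc"]],
           adj_r_squared = fit$adj_r_squared, F = fit$statistic,
           df = fit$df, p = fit$p)
    }, error = function(e) list(predictor = m, skipped = conditionMessage(e)))
  }
  outcomes <- if (!is.null(clinical) && "cgi_post" %in% names(clinical))
    classify_outcomes(clinical)
  list(paired_change = paired, change_correlation = chg,
       followup_regression = fup,
       outcomes = if (!is.null(outcomes)) as.list(outcomes$rates),
       thresholds = list(global = as.numeric(bonferroni_alpha(0.05, 3)),
                         secondary = as.numeric(bonferroni_alpha(0.05, 6)),
                         node_fdr_q = as.numeric(bonferroni_alpha(0.05, 4)),
                         exploratory = as.numeric(bonferroni_alpha(0.05, 12))),
       seed = cfg$seed)
}

write_report <- function(res, cfg, path) {
  lines <- c("# swnet pipeline report", "",
             sprintf("- seed: %d", cfg$seed),
             sprintf("- connectivity: %s (shrinkage %s)",
                     cfg$connectivity$method,
                     as.character(cfg$connectivity$shrinkage)),
             sprintf("- sparsity grid: %s",
                     paste(cfg$metrics$grid, collapse = ", ")),
             sprintf("- nulls per grid point: %d", cfg$metrics$n_rand),
             sprintf("- corrected alpha (global metrics): %.4f",
                     res$thresholds$global), "",
             "## Paired pre/post change (motion-residualized AUC)", "")
  for (pc in res$paired_change)
    lines <- c(lines, if (!is.null(pc$skipped))
      sprintf("- %s: skipped (%s)", pc$metric, pc$skipped)
      else sprintf("- %s: %s, p = %.4g (mean change %.4g)",
                   pc$metric, pc$method, pc$p, pc$mean_change))
  if (!is.null(res$followup_regression) &&
      is.null(res$followup_regression$skipped)) {
    fr <- res$followup_regression
    lines <- c(lines, "", "## Follow-up prediction",
               sprintf("- %s: adj R^2 = %.3f, F(%.0f,%.0f) = %.2f, p = %.4g",
                       fr$predictor, fr$adj_r_squared,
                       as.numeric(fr$df[[1]]), as.numeric(fr$df[[2]]),
                       as.numeric(fr$F), as.numeric(fr$p)))
  }
  if (!is.null(res$outcomes))
    lines <- c(lines, "", "## Clinical outcomes (%)",
               sprintf("- response %.1f, remission %.1f, worsening %.1f",
                       res$outcomes$response, res$outcomes$remission,
                       res$outcomes$worsening))
  writeLines(lines, path)
  invisible(path)
}
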