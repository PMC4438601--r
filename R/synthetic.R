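#' Generate node time series with planted modular correlation structure
#'
#' Factor-model construction: every node's series is a weighted sum of a
#' global latent signal (loading `sqrt(between_r)`), its module's latent
#' signal (loading `sqrt(within_r - between_r)`) and idiosyncratic noise
#' (sd `sqrt(1 - within_r)`), all i.i.d. standard normal over time, then
#' scaled by `noise_sd`. The expected pairwise correlation is therefore
#' exactly `within_r` inside a module and `between_r` across modules,
#' and the implied covariance is positive definite by construction.
#'
#' @param n_nodes,n_timepoints matrix dimensions.
#' @param membership integer module label per node.
#' @param within_r,between_r target correlations, `0 <= between_r <=
#'   within_r < 1`.
#' @param noise_sd overall amplitude scale.
#' @param seed integer seed.
#' @param tr sampling interval in seconds.
#' @return a [ts_matrix()].
#' @export
generate_modular_timeseries <- function(n_nodes, n_timepoints, membership,
                                        within_r, between_r, noise_sd = 1,
                                        seed = NULL, tr = 2) {
  n_nodes <- check_count(n_nodes, "n_nodes", lower = 2L)
  n_timepoints <- check_count(n_timepoints, "n_timepoints", lower = 3L)
  check_number(within_r, "within_r", lower = 0, upper = 1 - 1e-9)
  check_number(between_r, "between_r", lower = 0, upper = 1 - 1e-9)
  check_number(noise_sd, "noise_sd", lower = 1e-12)
  if (between_r > within_r)
    stopf(paste("between_r (%g) > within_r (%g) implies a non-positive-",
                "definite correlation structure under the factor model"),
          between_r, within_r)
  membership <- as.integer(factor(membership))
  if (length(membership) != n_nodes)
    stopf("membership must label all %d nodes", n_nodes)
  with_seed(seed, {
    g <- matrix(rnorm(n_timepoints), 1)                 # global latent
    f <- matrix(rnorm(max(membership) * n_timepoints),  # module latents
                max(membership))
    e <- matrix(rnorm(n_nodes * n_timepoints), n_nodes)
    X <- sqrt(between_r) * g[rep(1, n_nodes), , drop = FALSE] +
      sqrt(within_r - between_r) * f[membership, , drop = FALSE] +
      sqrt(1 - within_r) * e
    ts_matrix(noise_sd * X, tr = tr)
  })
}

#' Inject motion-artifact spikes
#'
#' Adds a global additive offset of `spike_amplitude` (signal units,
#' random sign) to every node at randomly selected volumes, emulating
#' sudden head motion; the spiked volume indices are recorded in the
#' `spike_volumes` attribute so DVARS-based QC can be validated against
#' ground truth.
#'
#' @param ts a [ts_matrix()].
#' @param spike_rate per-volume spike probability in \[0, 1\].
#' @param spike_amplitude offset magnitude (> 0), in signal units.
#' @param seed integer seed.
#' @return a [ts_matrix()] with attribute `spike_volumes`.
#' @export
inject_motion_spikes <- function(ts, spike_rate, spike_amplitude,
                                 seed = NULL) {
  check_number(spike_rate, "spike_rate", lower = 0, upper = 1)
  check_number(spike_amplitude, "spike_amplitude", lower = 1e-12)
  with_seed(seed, {
    hit <- which(runif(n_time(ts)) < spike_rate)
    if (length(hit)) {
      sgn <- sample(c(-1, 1), length(hit), replace = TRUE)
      ts$values[, hit] <- ts$values[, hit] +
        rep(sgn * spike_amplitude, each = n_nodes(ts))
    }
    attr(ts, "spike_volumes") <- hit
    ts
  })
}

#' Default clinical score distributions
#'
#' Means and SDs for the simulated instruments, calibrated to a small
#' adult OCD cohort treated with intensive CBT (YBOCS ~ 23.1 +/- 3.0
#' pre, 13.8 +/- 4.3 post; 1-12 month naturalistic follow-up, mean 7
#' months). Every element can be overridden through the
#' `clinical_params` argument of [cohort_spec()].
#'
#' @return named list of distribution parameters.
#' @export
default_clinical_params <- function() {
  list(ybocs_pre = c(mean = 23.12, sd = 3.04),
       ybocs_post = c(mean = 13.76, sd = 4.25),
       followup_shift = c(mean = 1.71),      # mean YBOCS drift post -> follow-up
       hama_pre = c(mean = 11.94, sd = 4.78),
       hama_post = c(mean = 8.06, sd = 4.66),
       madrs_pre = c(mean = 12.12, sd = 5.51),
       madrs_post = c(mean = 9.53, sd = 9.71),
       gas_pre = c(mean = 59.06, sd = 6.65),
       gas_post = c(mean = 74.06, sd = 13.66),
       stroop_pre = c(mean = 54.59, sd = 7.37),
       stroop_post = c(mean = 54.47, sd = 7.88),
       months_followup = c(mean = 7, sd = 4.53, min = 1, max = 12),
       p_medicated_followup = 6 / 17,
       p_cbt_followup = 10 / 17,
       cbt_sessions_mean = 8)
}

#' Specification of a synthetic scan + clinical cohort
#'
#' Captures every knob of the generator. Defaults emulate the study
#' design this package targets: 17 subjects, 160 nodes, 208 volumes at
#' TR = 2 s, modular resting-state correlation structure that
#' strengthens after treatment, motion spikes, and clinical scores whose
#' follow-up worsening carries a planted linear association
#' (`effect_beta`, YBOCS points per SD) with the subject's realized
#' pre-treatment small-worldness AUC.
#'
#' @param n_subjects,n_nodes,n_timepoints,tr cohort geometry.
#' @param n_modules planted module count (nodes split evenly).
#' @param within_r,between_r target correlations inside/across modules.
#' @param post_within_r_delta additive shift of `within_r` for the
#'   post-treatment session (> 0 raises clustering/small-worldness).
#' @param motion_spike_rate per-volume spike probability.
#' @param spike_amplitude spike offset in units of signal SD.
#' @param baseline constant signal offset (sets the DVARS percent
#'   scale; 15 gives clean-scan DVARS near 9.5%).
#' @param clinical_params overrides merged over
#'   [default_clinical_params()].
#' @param effect_beta planted slope of follow-up YBOCS change on the
#'   standardized realized pre-treatment small-worldness AUC.
#' @param outcome_noise_sd residual SD of follow-up change.
#' @param graph_grid,n_rand,shrinkage settings used when the generator
#'   computes realized small-worldness AUCs.
#' @param seed mandatory integer seed; identical specs with identical
#'   seeds yield bit-identical cohorts.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 17L, n_nodes = 160L,
                        n_timepoints = 208L, tr = 2, n_modules = 8L,
                        within_r = 0.35, between_r = 0.10,
                        post_within_r_delta = 0.05,
                        motion_spike_rate = 0.01, spike_amplitude = 5,
                        baseline = 15, clinical_params = list(),
                        effect_beta = 4, outcome_noise_sd = 3,
                        graph_grid = seq(0.1, 0.5, by = 0.05),
                        n_rand = 100L, shrinkage = "auto", seed) {
  if (missing(seed)) stopf("`seed` is mandatory for a cohort_spec")
  seed <- check_count(seed, "seed", lower = 0L)
  n_subjects <- check_count(n_subjects, "n_subjects")
  n_nodes <- check_count(n_nodes, "n_nodes", lower = 4L)
  n_timepoints <- check_count(n_timepoints, "n_timepoints", lower = 50L)
  n_modules <- check_count(n_modules, "n_modules")
  if (n_modules > n_nodes) stopf("n_modules cannot exceed n_nodes")
  check_number(within_r, "within_r", lower = 0, upper = 1 - 1e-9)
  check_number(between_r, "between_r", lower = 0, upper = 1 - 1e-9)
  if (between_r >= within_r && !(between_r == 0 && within_r == 0))
    stopf("require 0 <= between_r < within_r < 1")
  if (within_r + max(0, post_within_r_delta) >= 1)
    stopf("within_r + post_within_r_delta must stay below 1")
  check_number(motion_spike_rate, "motion_spike_rate", lower = 0, upper = 1)
  params <- modifyList(default_clinical_params(), clinical_params)
  structure(list(n_subjects = n_subjects, n_nodes = n_nodes,
                 n_timepoints = n_timepoints, tr = tr,
                 n_modules = n_modules, within_r = within_r,
                 between_r = between_r,
                 post_within_r_delta = post_within_r_delta,
                 motion_spike_rate = motion_spike_rate,
                 spike_amplitude = spike_amplitude, baseline = baseline,
                 clinical_params = params, effect_beta = effect_beta,
                 outcome_noise_sd = outcome_noise_sd,
                 graph_grid = graph_grid, n_rand = n_rand,
                 shrinkage = shrinkage, seed = seed),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d subjects, %d nodes x %d volumes ",
                     "(TR %gs), %d modules\n  r(within) = %.2f -> %.2f ",
                     "post, r(between) = %.2f, effect_beta = %g, ",
                     "seed = %d\n"),
              x$n_subjects, x$n_nodes, x$n_timepoints, x$tr, x$n_modules,
              x$within_r, x$within_r + x$post_within_r_delta, x$between_r,
              x$effect_beta, x$seed))
  invisible(x)
}

round_clamp <- function(x, lo, hi, what) {
  x <- round(x)
  out <- pmin(hi, pmax(lo, x))
  if (any(out != x))
    warnf("%d %s value(s) outside [%g, %g]; clamped", sum(out != x), what,
          lo, hi)
  out
}

#' Generate a synthetic cohort
#'
#' Produces pre- and post-treatment scans per subject (the post session
#' uses `within_r + post_within_r_delta`, so clustering and
#' small-worldness rise when the delta is positive), motion spikes,
#' scan-level DVARS, and a clinical table. When `effect_beta != 0` the
#' generator runs the connectivity + graph-metric pipeline on each
#' subject's pre-treatment scan to obtain the realized small-worldness
#' AUC, standardizes it within the cohort, and plants
#' `effect_beta * z(AUC)` into the follow-up YBOCS change (plus Gaussian
#' noise); response, remission and worsening labels are then derivable
#' from the scores. Scores are rounded to integers and clamped to
#' instrument ranges.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `synthetic_cohort`: list with
#'   `timeseries` (per subject, `$pre` and `$post` [ts_matrix()]),
#'   `membership`, `clinical` (data.frame), `realized_sigma_auc` (or
#'   `NULL`), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  membership <- sort(rep_len(seq_len(spec$n_modules), spec$n_nodes))
  scans <- vector("list", n)
  dvars_pre <- dvars_post <- numeric(n)
  for (s in seq_len(n)) {
    pair <- list()
    for (sess in c("pre", "post")) {
      wr <- spec$within_r +
        if (sess == "post") spec$post_within_r_delta else 0
      ts <- generate_modular_timeseries(
        spec$n_nodes, spec$n_timepoints, membership, wr, spec$between_r,
        seed = seed_stream(spec$seed, s, match(sess, c("pre", "post"))),
        tr = spec$tr)
      ts$values <- ts$values + spec$baseline
      if (spec$motion_spike_rate > 0)
        ts <- inject_motion_spikes(
          ts, spec$motion_spike_rate, spec$spike_amplitude,
          seed = seed_stream(spec$seed, s,
                             match(sess, c("pre", "post")), 99L))
      ts$subject_id <- sprintf("sub%03d", s)
      ts$session <- sess
      pair[[sess]] <- ts
    }
    scans[[s]] <- pair
    dvars_pre[s] <- compute_dvars(pair$pre)$dvars_mean
    dvars_post[s] <- compute_dvars(pair$post)$dvars_mean
  }

  realized <- NULL
  z_auc <- rep(0, n)
  if (spec$effect_beta != 0) {
    sig <- vapply(seq_len(n), function(s) {
      Cm <- partial_correlation_matrix(scans[[s]]$pre,
                                       shrinkage = spec$shrinkage)
      curves <- metric_curves(Cm, grid = spec$graph_grid,
                              n_rand = spec$n_rand,
                              seed = seed_stream(spec$seed, s, 5L),
                              metrics = "sigma")
      auc_table(curves)$auc[1]
    }, 1.0)
    realized <- data.frame(subject_id = sprintf("sub%03d", seq_len(n)),
                           sigma_auc = sig)
    z_auc <- if (n > 1 && sd(sig) > 0) (sig - mean(sig)) / sd(sig)
             else rep(0, n)
  }

  p <- spec$clinical_params
  clinical <- with_seed(seed_stream(spec$seed, 424243L), {
    ybocs_pre <- round_clamp(rnorm(n, p$ybocs_pre["mean"],
                                   p$ybocs_pre["sd"]), 0, 40, "YBOCS pre")
    ybocs_post <- round_clamp(rnorm(n, p$ybocs_post["mean"],
                                    p$ybocs_post["sd"]), 0, 40,
                              "YBOCS post")
    reduction <- (ybocs_pre - ybocs_post) / pmax(ybocs_pre, 1)
    cgi_post <- round_clamp(4.25 - 5 * reduction + rnorm(n, 0, 0.5), 1, 7,
                            "CGI")
    months_followup <- pmin(p$months_followup["max"],
                            pmax(p$months_followup["min"],
                                 round(rnorm(n, p$months_followup["mean"],
                                             p$months_followup["sd"]))))
    medicated <- rbinom(n, 1, p$p_medicated_followup)
    medication_months <- medicated * pmax(1, round(runif(n) *
                                                     months_followup))
    cbt <- rbinom(n, 1, p$p_cbt_followup)
    cbt_sessions <- cbt * stats::rpois(n, p$cbt_sessions_mean)
    delta_fu <- p$followup_shift["mean"] + spec$effect_beta * z_auc +
      rnorm(n, 0, spec$outcome_noise_sd)
    ybocs_followup <- round_clamp(ybocs_post + delta_fu, 0, 40,
                                  "YBOCS follow-up")
    data.frame(subject_id = sprintf("sub%03d", seq_len(n)),
               ybocs_pre = ybocs_pre, ybocs_post = ybocs_post,
               ybocs_followup = ybocs_followup, cgi_post = cgi_post,
               hama_pre = round_clamp(rnorm(n, p$hama_pre["mean"],
                                            p$hama_pre["sd"]), 0, 56,
                                      "HAMA"),
               hama_post = round_clamp(rnorm(n, p$hama_post["mean"],
                                             p$hama_post["sd"]), 0, 56,
                                       "HAMA"),
               madrs_pre = round_clamp(rnorm(n, p$madrs_pre["mean"],
                                             p$madrs_pre["sd"]), 0, 60,
                                       "MADRS"),
               madrs_post = round_clamp(rnorm(n, p$madrs_post["mean"],
                                              p$madrs_post["sd"]), 0, 60,
                                        "MADRS"),
               gas_pre = round_clamp(rnorm(n, p$gas_pre["mean"],
                                           p$gas_pre["sd"]), 1, 100, "GAS"),
               gas_post = round_clamp(rnorm(n, p$gas_post["mean"],
                                            p$gas_post["sd"]), 1, 100,
                                      "GAS"),
               stroop_pre = round(rnorm(n, p$stroop_pre["mean"],
                                        p$stroop_pre["sd"])),
               stroop_post = round(rnorm(n, p$stroop_post["mean"],
                                         p$stroop_post["sd"])),
               months_followup = months_followup,
               medication_months = medication_months,
               cbt_sessions = cbt_sessions,
               dvars_pre = dvars_pre, dvars_post = dvars_post,
               row.names = NULL)
  })
  structure(list(timeseries = scans, membership = membership,
                 clinical = clinical, realized_sigma_auc = realized,
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort> %d subjects x 2 sessions, ",
                     "%d nodes x %d volumes (seed %d)\n"),
              x$spec$n_subjects, x$spec$n_nodes, x$spec$n_timepoints,
              x$spec$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Per-scan time series as tab-delimited text
#' (`<subject>_<session>.tsv`), the clinical table as
#' `clinical.csv`, and provenance (spec + seed) as `cohort.json`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pair in cohort$timeseries)
    for (ts in pair)
      write_timeseries(ts, file.path(dir, sprintf("%s_%s.tsv",
                                                  ts$subject_id,
                                                  ts$session)))
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE)
  spec <- cohort$spec
  spec$clinical_params <- lapply(spec$clinical_params, as.list)
  jsonlite::write_json(c(unclass(spec),
                         list(membership = cohort$membership)),
                       file.path(dir, "cohort.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Connectivity + metric AUCs for every scan of a cohort
#'
#' Convenience orchestration used by the pipeline and validation
#' studies: for each scan, estimates the connectivity matrix, evaluates
#' metric curves on the sparsity grid, and integrates them to AUCs.
#'
#' @param cohort a `synthetic_cohort` (or any list of per-subject
#'   `list(pre = , post = )` [ts_matrix()] pairs in `$timeseries`).
#' @param grid,n_rand,metrics,n_restarts passed to [metric_curves()].
#' @param method `"partial"` or `"pearson"`.
#' @param shrinkage passed to [partial_correlation_matrix()].
#' @param seed master seed; per-scan streams are derived from it.
#' @param preprocess logical: apply [preprocess_timeseries()] (band-pass
#'   + discard) before connectivity. Off by default for synthetic
#'   cohorts, whose series are generated clean.
#' @param k_discard volumes to drop when preprocessing.
#' @param sessions which sessions to analyse (default both).
#' @return list with `auc` (an `auc_table`) and `dvars` (per-scan
#'   data.frame).
#' @export
cohort_metrics <- function(cohort, grid = seq(0.1, 0.5, by = 0.05),
                           n_rand = 100L, metrics = c("C", "sigma"),
                           method = c("partial", "pearson"),
                           shrinkage = "auto", seed = 1L,
                           preprocess = FALSE, k_discard = 2L,
                           n_restarts = 20L, sessions = c("pre", "post")) {
  method <- match.arg(method)
  aucs <- list()
  dv <- list()
  for (s in seq_along(cohort$timeseries)) {
    for (sess in intersect(names(cohort$timeseries[[s]]), sessions)) {
      ts <- cohort$timeseries[[s]][[sess]]
      qc <- compute_dvars(ts)
      if (preprocess) {
        pp <- preprocess_timeseries(ts, k_discard = k_discard)
        ts <- pp$ts
        qc <- pp$qc
      }
      Cm <- if (method == "partial")
        partial_correlation_matrix(ts, shrinkage = shrinkage)
      else pearson_matrix(ts)
      curves <- metric_curves(Cm, grid = grid, n_rand = n_rand,
                              seed = seed_stream(seed, s,
                                                 match(sess,
                                                       c("pre", "post"))),
                              metrics = metrics, n_restarts = n_restarts)
      aucs[[length(aucs) + 1L]] <- auc_table(curves,
                                             subject_id = ts$subject_id,
                                             session = sess)
      dv[[length(dv) + 1L]] <- data.frame(subject_id = ts$subject_id,
                                          session = sess,
                                          dvars = qc$dvars_mean)
    }
  }
  out <- do.call(rbind, aucs)
  class(out) <- c("auc_table", "data.frame")
  list(auc = out, dvars = do.call(rbind, dv))
}
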