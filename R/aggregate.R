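#' Area under a metric curve
#'
#' Trapezoidal integral of a metric over the sparsity grid, giving a
#' threshold-free per-subject summary (e.g. a constant curve `c` on
#' \[0.1, 0.5\] integrates to `0.4 * c`).
#'
#' @param values metric values at `grid`.
#' @param grid sorted sparsity grid, length >= 2.
#' @return scalar AUC.
#' @export
auc <- function(values, grid) {
  if (length(grid) < 2L) stopf("AUC needs a grid of length >= 2")
  if (length(values) != length(grid)) stopf("values/grid length mismatch")
  if (is.unsorted(grid, strictly = TRUE)) stopf("grid must be sorted")
  pracma::trapz(grid, values)
}

#' AUC table from metric curves
#'
#' Integrates every metric of a [metric_curves()] object and returns one
#' row per metric, tagged with subject and session.
#'
#' @param curves a [metric_curves()] object.
#' @param subject_id,session identifying labels.
#' @return data.frame of class `auc_table` with columns `subject_id`,
#'   `session`, `metric`, `auc`.
#' @export
auc_table <- function(curves, subject_id = NA_character_,
                      session = NA_character_) {
  mets <- unique(curves$metric)
  rows <- lapply(mets, function(m) {
    d <- curves[curves$metric == m, ]
    d <- d[order(d$sparsity), ]
    data.frame(subject_id = subject_id, session = session, metric = m,
               auc = auc(d$value, d$sparsity))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("auc_table", "data.frame")
  out
}

#' Residualize AUCs on head motion
#'
#' For each metric, regresses AUC on the scan-level DVARS value across
#' all scans and replaces AUCs by residual + grand mean, removing the
#' confounding effect of motion before group statistics. With
#' zero-variance DVARS the table is returned unchanged with a warning.
#'
#' @param auc_tab an [auc_table()] (rows = subject x session x metric).
#' @param dvars data.frame with columns `subject_id`, `session`, `dvars`
#'   (one row per scan).
#' @return the adjusted `auc_table`.
#' @export
residualize_on_motion <- function(auc_tab, dvars) {
  key <- paste(auc_tab$subject_id, auc_tab$session)
  dkey <- paste(dvars$subject_id, dvars$session)
  idx <- match(key, dkey)
  if (anyNA(idx)) stopf("missing DVARS for scan(s): %s",
                        paste(unique(key[is.na(idx)]), collapse = ", "))
  x <- dvars$dvars[idx]
  if (var(x) < 1e-20) {
    warnf("DVARS has zero variance; returning AUCs unchanged")
    return(auc_tab)
  }
  for (m in unique(auc_tab$metric)) {
    sel <- auc_tab$metric == m
    fit <- lm(auc_tab$auc[sel] ~ x[sel])
    auc_tab$auc[sel] <- residuals(fit) + mean(auc_tab$auc[sel])
  }
  auc_tab
}

stat_result <- function(method, statistic, df, p, effect = NA_real_,
                        effect_type = NA_character_, n = NA_integer_,
                        seed = NULL, alpha_corrected = NA_real_,
                        extra = list()) {
  structure(c(list(method = method, statistic = statistic, df = df, p = p,
                   effect = effect, effect_type = effect_type, n = n,
                   seed = seed, alpha_corrected = alpha_corrected), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: stat = %.4g, df = %s, p = %.4g",
              x$method, x$statistic,
              paste(signif(x$df, 4), collapse = ","), x$p))
  if (!is.na(x$effect))
    cat(sprintf(", %s = %.4g", x$effect_type, x$effect))
  cat(sprintf(" (n = %d)\n", x$n))
  invisible(x)
}

#' Paired pre/post change test with permutation fallback
#'
#' Tests whether paired measurements changed between sessions. A
#' Shapiro-Wilk test on the paired differences (at `normality_alpha`)
#' selects the branch: a paired t-test for normal-looking differences,
#' otherwise a two-sided one-sample sign-flip permutation test on the
#' differences. The permutation branch enumerates all `2^n` sign
#' patterns exhaustively when `2^n <= max_exhaustive` (always true at
#' small cohort sizes), otherwise it samples `n_perm` patterns and
#' applies the add-one correction `p = (1 + #extreme) / (1 + n_perm)`.
#'
#' @param pre,post equal-length paired numeric vectors (n >= 3).
#' @param normality_alpha Shapiro-Wilk branching level.
#' @param n_perm Monte-Carlo permutations when not exhaustive.
#' @param max_exhaustive enumerate all sign patterns when `2^n` is at
#'   most this.
#' @param seed integer seed (Monte-Carlo branch only).
#' @return a `stat_result`; `$method` records the branch taken
#'   (`"paired t"`, `"sign-flip permutation (exhaustive)"` or
#'   `"sign-flip permutation (monte carlo)"`); `$effect` is the mean
#'   difference `post - pre`.
#' @export
paired_change_test <- function(pre, post, normality_alpha = 0.05,
                               n_perm = 10000L, max_exhaustive = 65536L,
                               seed = NULL) {
  if (length(pre) != length(post)) stopf("pre/post length mismatch")
  n <- length(pre)
  if (n < 3L) stopf("need at least 3 pairs")
  d <- post - pre
  if (var(d) < 1e-24)
    return(stat_result("degenerate (zero-variance differences)", 0, n - 1, 1,
                       effect = mean(d), effect_type = "mean difference",
                       n = n))
  sw_p <- shapiro.test(d)$p.value
  if (sw_p >= normality_alpha) {
    tt <- t.test(post, pre, paired = TRUE)
    return(stat_result("paired t", unname(tt$statistic),
                       unname(tt$parameter), tt$p.value, effect = mean(d),
                       effect_type = "mean difference", n = n,
                       extra = list(shapiro_p = sw_p)))
  }
  obs <- mean(d)
  if (2^n <= max_exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    perm <- as.numeric(signs %*% d) / n
    p <- mean(abs(perm) >= abs(obs) - 1e-12)
    method <- "sign-flip permutation (exhaustive)"
    seed_used <- NULL
  } else {
    perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i)
        mean(sample(c(-1, 1), n, replace = TRUE) * d), 1.0)
    })
    p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (1 + n_perm)
    method <- "sign-flip permutation (monte carlo)"
    seed_used <- seed
  }
  stat_result(method, obs, NA_real_, p, effect = obs,
              effect_type = "mean difference", n = n, seed = seed_used,
              extra = list(shapiro_p = sw_p))
}

#' Partial correlation with covariate control
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing
#' each on the covariates (plus intercept); the p value is t-based with
#' `df = n - n_covariates - 2`. With no covariates this is the plain
#' Pearson correlation test.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric matrix/data.frame (n rows).
#' @return a `stat_result` with `$effect` = partial r.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stopf("x/y length mismatch")
  k <- 0L
  if (!is.null(covariates)) {
    Z <- as.matrix(covariates)
    if (nrow(Z) != n) stopf("covariates must have %d rows", n)
    k <- ncol(Z)
    if (n <= k + 2L) stopf("need n > n_covariates + 2")
    if (qr(cbind(1, Z))$rank < k + 1L) stopf("covariates are rank deficient")
    x <- residuals(lm(x ~ Z))
    y <- residuals(lm(y ~ Z))
  }
  r <- cor(x, y)
  df <- n - k - 2L
  tt <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tt), df)
  stat_result(if (k) sprintf("partial correlation (%d covariates)", k)
              else "Pearson correlation", tt, df, p, effect = r,
              effect_type = "r", n = n)
}

#' Predict follow-up symptom change from a pre-treatment network metric
#'
#' Ordinary least-squares regression of follow-up symptom worsening,
#' `delta = ybocs_followup - ybocs_post` (positive = worsening), on a
#' pre-treatment graph-metric AUC plus the four follow-up covariates of
#' no interest: months to follow-up, months of medication in follow-up,
#' CBT sessions in follow-up, and pre-treatment scan DVARS. Reports the
#' overall F on (5, n - 6) df and the adjusted R-squared
#' `1 - (1 - R2)(n - 1)/(n - p - 1)`.
#'
#' @param clinical data.frame with columns `ybocs_post`,
#'   `ybocs_followup`, `months_followup`, `medication_months`,
#'   `cbt_sessions`, `dvars_pre` (see [generate_cohort()] for the
#'   dictionary).
#' @param predictor_auc numeric vector, one pre-treatment AUC per
#'   subject (same order as `clinical`).
#' @param predictor_name label for printing.
#' @param max_condition condition-number bound on the scaled design;
#'   beyond it the fit fails as collinear.
#' @return an object of class `followup_fit` with `print`, `summary`,
#'   `coef`, `predict`, `residuals` and `plot` methods; fields include
#'   `statistic` (F), `df`, `p`, `adj_r_squared` and the underlying
#'   `lm` fit.
#' @export
fit_followup_regression <- function(clinical, predictor_auc,
                                    predictor_name = "metric_auc",
                                    max_condition = 1e10) {
  need <- c("ybocs_post", "ybocs_followup", "months_followup",
            "medication_months", "cbt_sessions", "dvars_pre")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stopf("clinical table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  n <- nrow(clinical)
  if (length(predictor_auc) != n) stopf("predictor_auc must have %d values", n)
  d <- data.frame(delta = clinical$ybocs_followup - clinical$ybocs_post,
                  auc = predictor_auc,
                  months_followup = clinical$months_followup,
                  medication_months = clinical$medication_months,
                  cbt_sessions = clinical$cbt_sessions,
                  dvars_pre = clinical$dvars_pre)
  if (anyNA(d)) stopf("complete cases required")
  if (n <= 6L) stopf("need n > 6 (5 predictors + intercept)")
  X <- scale(as.matrix(d[, -1]))
  kap <- kappa(cbind(1, X), exact = TRUE)
  if (!is.finite(kap) || kap > max_condition)
    stopf("design is (near-)collinear: condition number %.3g", kap)
  fit <- lm(delta ~ auc + months_followup + medication_months +
              cbt_sessions + dvars_pre, data = d)
  sm <- summary(fit)
  f <- unname(sm$fstatistic)
  p <- pf(f[1], f[2], f[3], lower.tail = FALSE)
  structure(list(fit = fit, predictor_name = predictor_name,
                 statistic = f[1], df = c(f[2], f[3]), p = p,
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 coefficients = coef(fit), n = n, condition_number = kap),
            class = "followup_fit")
}

#' @export
print.followup_fit <- function(x, ...) {
  cat(sprintf(paste0("<followup_fit> delta-YBOCS ~ %s + 4 covariates\n",
                     "  adjusted R^2 = %.3f, F(%.0f,%.0f) = %.2f, p = %.4g ",
                     "(n = %d)\n  %s coefficient = %.4g\n"),
              x$predictor_name, x$adj_r_squared, x$df[1], x$df[2],
              x$statistic, x$p, x$n, x$predictor_name,
              x$coefficients[["auc"]]))
  invisible(x)
}

#' @export
summary.followup_fit <- function(object, ...) summary(object$fit, ...)

#' @export
coef.followup_fit <- function(object, ...) coef(object$fit, ...)

#' @export
predict.followup_fit <- function(object, ...) predict(object$fit, ...)

#' @export
residuals.followup_fit <- function(object, ...) residuals(object$fit, ...)

#' @export
plot.followup_fit <- function(x, ...) {
  obs <- x$fit$model$delta
  pred <- predict(x$fit)
  plot(pred, obs, xlab = "predicted delta-YBOCS (follow-up - post)",
       ylab = "observed delta-YBOCS",
       main = sprintf("%s: adj R^2 = %.2f", x$predictor_name,
                      x$adj_r_squared), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' `family_alpha / m`, with the conventionally printed rounding attached
#' (e.g. 0.05/3 prints as 0.017 at 3 decimals).
#'
#' @param family_alpha family-wise level.
#' @param m number of independent tests (>= 1).
#' @param digits decimals for the printed form.
#' @return the exact threshold, with attribute `printed`.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, m = 1L, digits = 3L) {
  m <- check_count(m, "m")
  check_number(family_alpha, "family_alpha", lower = 0, upper = 1)
  val <- family_alpha / m
  structure(val, printed = round(val, digits))
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure at level `q`: returns the indices rejected and the
#' BH-adjusted p values (via `stats::p.adjust`).
#'
#' @param pvalues p values in \[0, 1\].
#' @param q FDR level.
#' @return list with `rejected` (integer indices), `adjusted`, `q`.
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (!length(pvalues)) return(list(rejected = integer(),
                                    adjusted = numeric(), q = q))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stopf("p values must lie in [0, 1]")
  adj <- p.adjust(pvalues, method = "BH")
  list(rejected = which(adj <= q), adjusted = adj, q = q)
}

#' Clinical outcome classification
#'
#' Applies the standard operational definitions to each subject:
#' response is a YBOCS reduction of at least 35% pre to post AND a CGI
#' of at most 2; remission is a post YBOCS of at most 14; clinically
#' significant worsening is a YBOCS increase of at least 5 points from
#' post-treatment to follow-up.
#'
#' @param clinical data.frame with `ybocs_pre`, `ybocs_post`, `cgi_post`
#'   and (optionally) `ybocs_followup`.
#' @return list with `flags` (per-subject data.frame: `pct_change`,
#'   `responder`, `remitter`, `worsened`) and `rates` (percent of
#'   subjects in each category).
#' @export
classify_outcomes <- function(clinical) {
  need <- c("ybocs_pre", "ybocs_post", "cgi_post")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stopf("clinical table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(clinical$ybocs_pre <= 0))
    stopf("percent change undefined: ybocs_pre must be > 0")
  pct <- 100 * (clinical$ybocs_pre - clinical$ybocs_post) /
    clinical$ybocs_pre
  responder <- pct >= 35 & clinical$cgi_post <= 2
  remitter <- clinical$ybocs_post <= 14
  worsened <- if ("ybocs_followup" %in% names(clinical))
    (clinical$ybocs_followup - clinical$ybocs_post) >= 5
  else rep(NA, nrow(clinical))
  flags <- data.frame(subject_id = clinical$subject_id %||%
                        seq_len(nrow(clinical)),
                      pct_change = pct, responder = responder,
                      remitter = remitter, worsened = worsened)
  list(flags = flags,
       rates = c(response = 100 * mean(responder),
                 remission = 100 * mean(remitter),
                 worsening = 100 * mean(worsened)))
}

#' Node-level pre/post change analysis
#'
#' Runs [paired_change_test()] per node on a subjects x nodes matrix of
#' a node metric for each session, then controls FDR within the metric
#' at level `q` (convention: 0.05/4 = 0.0125 across four independent
#' node-metric families). The full table is returned regardless of
#' significance.
#'
#' @param pre,post subjects x nodes matrices, identical dimnames.
#' @param q FDR level within the metric.
#' @param ... passed to [paired_change_test()].
#' @return data.frame with one row per node (`node`, `statistic`, `p`,
#'   `p_adjusted`, `rejected`, `method`).
#' @export
node_level_change_analysis <- function(pre, post, q = 0.0125, ...) {
  pre <- as.matrix(pre)
  post <- as.matrix(post)
  if (!identical(dim(pre), dim(post)))
    stopf("pre/post node matrices differ in shape")
  if (!identical(colnames(pre), colnames(post)))
    stopf("pre/post node sets differ")
  nodes <- colnames(pre) %||% sprintf("n%03d", seq_len(ncol(pre)))
  res <- lapply(seq_len(ncol(pre)), function(j)
    paired_change_test(pre[, j], post[, j], ...))
  p <- vapply(res, `[[`, 1.0, "p")
  bh <- fdr_bh(p, q)
  data.frame(node = nodes,
             statistic = vapply(res, `[[`, 1.0, "statistic"),
             p = p, p_adjusted = bh$adjusted,
             rejected = seq_along(p) %in% bh$rejected,
             method = vapply(res, `[[`, "", "method"))
}
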