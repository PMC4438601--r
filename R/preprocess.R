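#' Discard initial volumes
#'
#' Drops the first `k` volumes of a scan, the usual guard against
#' pre-equilibrium magnetization (e.g. a 210-volume scan at TR = 2 s with
#' the first two volumes dropped gives the 208 analysed volumes).
#'
#' @param ts a [ts_matrix()].
#' @param k number of leading volumes to drop; must leave at least 3.
#' @return a [ts_matrix()] with `k` fewer volumes.
#' @export
discard_initial_volumes <- function(ts, k = 2L) {
  k <- check_count(k, "k", lower = 0L)
  if (k >= n_time(ts) - 2L)
    stopf("k = %d leaves fewer than 3 of %d volumes", k, n_time(ts))
  if (k == 0L) return(ts)
  ts$values <- ts$values[, -seq_len(k), drop = FALSE]
  ts
}

#' Band-pass filter node time series
#'
#' Zero-phase temporal band-pass filtering, by default retaining the
#' 0.009-0.08 Hz band conventionally used for resting-state BOLD. A
#' Butterworth design (order `order` per pass) is applied forward and
#' backward (`signal::filtfilt`), doubling the effective order and
#' cancelling phase distortion. DC is in the stopband, so each node's
#' output is (numerically) zero-mean.
#'
#' @param ts a [ts_matrix()].
#' @param low_hz,high_hz passband edges in Hz; `high_hz` must be below
#'   the Nyquist frequency `1/(2 * tr)`.
#' @param order Butterworth order per pass.
#' @return filtered [ts_matrix()].
#' @export
bandpass_filter <- function(ts, low_hz = 0.009, high_hz = 0.08, order = 2L) {
  nyq <- 1 / (2 * ts$tr)
  check_number(low_hz, "low_hz", lower = 0)
  check_number(high_hz, "high_hz")
  if (low_hz >= high_hz) stopf("low_hz must be < high_hz")
  if (high_hz >= nyq)
    stopf("high_hz = %g Hz is not below Nyquist = %g Hz", high_hz, nyq)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  # demean first: the DC offset is far outside the passband and would
  # otherwise leak in through filter edge transients
  out <- t(apply(ts$values - rowMeans(ts$values), 1L,
                 function(x) signal::filtfilt(bf, x)))
  dimnames(out) <- dimnames(ts$values)
  ts$values <- out
  ts
}

#' Assemble a nuisance-regressor set
#'
#' Binds the standard per-volume confounds (six rigid-body motion
#' parameters, white-matter and CSF mean signals) and augments each with
#' its temporal derivative (backward difference, first element 0).
#' Constant-zero columns arising from the augmentation are dropped with a
#' warning unless `keep_zero_cols = TRUE`.
#'
#' @param motion optional n_time x 6 matrix of motion parameters.
#' @param wm,csf optional length-n_time white-matter / CSF signals.
#' @param extra optional additional regressor matrix.
#' @param add_derivatives add backward-difference temporal derivatives.
#' @param keep_zero_cols keep all-zero columns instead of dropping them.
#' @return a numeric matrix of class `confound_set`, one column per
#'   regressor.
#' @export
confound_set <- function(motion = NULL, wm = NULL, csf = NULL, extra = NULL,
                         add_derivatives = TRUE, keep_zero_cols = FALSE) {
  parts <- list()
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (ncol(motion) != 6L) stopf("`motion` must have 6 columns")
    colnames(motion) <- sprintf("motion%d", 1:6)
    parts$motion <- motion
  }
  if (!is.null(wm)) parts$wm <- matrix(wm, ncol = 1, dimnames = list(NULL, "wm"))
  if (!is.null(csf)) parts$csf <- matrix(csf, ncol = 1, dimnames = list(NULL, "csf"))
  if (!is.null(extra)) parts$extra <- as.matrix(extra)
  if (!length(parts)) stopf("no regressors supplied")
  X <- do.call(cbind, unname(parts))
  nt <- unique(vapply(parts, nrow, 1L))
  if (length(nt) != 1L) stopf("regressors have differing lengths")
  if (add_derivatives) {
    D <- rbind(0, diff(X))
    colnames(D) <- paste0("d_", colnames(X))
    X <- cbind(X, D)
  }
  zero <- apply(X, 2L, function(v) all(v == 0))
  if (any(zero) && !keep_zero_cols) {
    warnf("dropping %d constant-zero confound column(s): %s", sum(zero),
          paste(colnames(X)[zero], collapse = ", "))
    X <- X[, !zero, drop = FALSE]
  }
  structure(X, class = c("confound_set", "matrix"))
}

#' Regress confounds out of node time series
#'
#' Removes each confound column (plus an intercept) from every node's
#' series by ordinary least squares, returning the residuals. The
#' residuals are orthogonal to every confound; with confounds orthogonal
#' to the data the output is simply the demeaned input.
#'
#' @param ts a [ts_matrix()].
#' @param confounds a [confound_set()] or numeric matrix with one row per
#'   volume.
#' @param on_rank_deficient `"drop"` (default) removes linearly dependent
#'   columns with a warning; `"fail"` stops.
#' @return residual [ts_matrix()].
#' @export
regress_confounds <- function(ts, confounds,
                              on_rank_deficient = c("drop", "fail")) {
  on_rank_deficient <- match.arg(on_rank_deficient)
  X <- as.matrix(confounds)
  if (nrow(X) != n_time(ts))
    stopf("confounds have %d rows but the scan has %d volumes",
          nrow(X), n_time(ts))
  X <- cbind(intercept = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    if (on_rank_deficient == "fail")
      stopf("confound matrix is rank deficient (dependent: %s)",
            paste(dropped, collapse = ", "))
    warnf("dropping %d linearly dependent confound column(s): %s",
          length(dropped), paste(dropped, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  Y <- t(ts$values)
  res <- Y - X %*% qr.coef(qrX, Y)
  ts$values <- t(res)
  rownames(ts$values) <- ts$node_ids
  ts
}

#' DVARS quality control
#'
#' DVARS is the root-mean-square change in signal from each volume to the
#' next: `dvars_t = sqrt(mean_nodes((x[,t] - x[,t-1])^2))`. In the default
#' `"percent"` scale it is expressed as a percentage of the scan's grand
#' mean absolute signal, so that a whole-scan mean DVARS can be held
#' against an exclusion threshold (default 25%). If the grand mean
#' absolute signal is numerically zero (for example after band-pass
#' filtering removed the baseline) the percent scale is undefined; raw
#' units are then reported with a warning.
#'
#' @param ts a [ts_matrix()].
#' @param scale `"percent"` (of grand mean absolute signal) or `"raw"`.
#' @param threshold exclusion threshold for the mean DVARS, in the chosen
#'   scale's units.
#' @return an object of class `qc_report` with fields `dvars_series`
#'   (length `n_time - 1`), `dvars_mean`, `excluded`, `threshold`,
#'   `scale`.
#' @examples
#' ts <- ts_matrix(matrix(c(1, 1, 4, 5, 4, 5), nrow = 2), tr = 2)
#' compute_dvars(ts, scale = "raw")$dvars_series[1]  # sqrt((9+16)/2)
#' @export
compute_dvars <- function(ts, scale = c("percent", "raw"), threshold = 25) {
  scale <- match.arg(scale)
  if (n_time(ts) < 2L) stopf("need at least 2 volumes")
  d <- diff(t(ts$values))            # (n_time-1) x nodes
  dv <- sqrt(rowMeans(d^2))
  if (scale == "percent") {
    gm <- mean(abs(ts$values))
    if (gm < 1e-12) {
      warnf("grand mean absolute signal ~ 0; reporting DVARS in raw units")
      scale <- "raw"
    } else dv <- 100 * dv / gm
  }
  m <- mean(dv)
  structure(list(dvars_series = as.numeric(dv), dvars_mean = m,
                 excluded = m > threshold, threshold = threshold,
                 scale = scale),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> mean DVARS = %.3f %s (threshold %g) -> %s\n",
              x$dvars_mean, if (x$scale == "percent") "%" else "(raw)",
              x$threshold,
              if (x$excluded) "EXCLUDE" else "keep"))
  invisible(x)
}

#' Run the temporal preprocessing pipeline on one scan
#'
#' Fixed stage order: discard initial volumes, (optional) band-pass
#' filter, (optional) confound regression, DVARS quality control. By
#' default DVARS is computed on the raw post-discard series, where the
#' percent-of-mean-signal scale is well defined; set
#' `dvars_stage = "cleaned"` to compute it on the fully cleaned series
#' instead (reported in raw units when the cleaned baseline is zero).
#'
#' @param ts a [ts_matrix()].
#' @param k_discard leading volumes to drop.
#' @param filter logical; apply [bandpass_filter()].
#' @param low_hz,high_hz passband edges.
#' @param confounds optional [confound_set()].
#' @param dvars_stage `"raw"` or `"cleaned"`.
#' @param dvars_threshold exclusion threshold (percent).
#' @return list with elements `ts` (cleaned scan), `qc`
#'   ([compute_dvars()] report) and `stages` (character log of the stages
#'   applied, in order).
#' @export
preprocess_timeseries <- function(ts, k_discard = 2L, filter = TRUE,
                                  low_hz = 0.009, high_hz = 0.08,
                                  confounds = NULL,
                                  dvars_stage = c("raw", "cleaned"),
                                  dvars_threshold = 25) {
  dvars_stage <- match.arg(dvars_stage)
  stages <- character()
  ts <- discard_initial_volumes(ts, k_discard)
  stages <- c(stages, sprintf("discard_initial_volumes(k=%d)", k_discard))
  raw <- ts
  if (filter) {
    ts <- bandpass_filter(ts, low_hz, high_hz)
    stages <- c(stages, sprintf("bandpass_filter(%g-%g Hz)", low_hz, high_hz))
  }
  if (!is.null(confounds)) {
    ts <- regress_confounds(ts, confounds)
    stages <- c(stages, "regress_confounds")
  }
  qc_src <- if (dvars_stage == "raw") raw else ts
  qc <- compute_dvars(qc_src, threshold = dvars_threshold)
  stages <- c(stages, sprintf("compute_dvars(stage=%s)", dvars_stage))
  list(ts = ts, qc = qc, stages = stages)
}
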