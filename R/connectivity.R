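#' Weighted connectivity matrix
#'
#' Symmetric node x node association matrix with an exactly zero diagonal
#' (so that proportional thresholding never selects self-connections).
#'
#' @param values symmetric numeric matrix; off-diagonals in `[-1, 1]`.
#' @param method `"partial"` or `"pearson"`.
#' @param node_ids node labels.
#' @param shrinkage shrinkage intensity actually applied (0 for Pearson).
#' @return an object of class `conn_matrix`.
#' @export
conn_matrix <- function(values, method = c("partial", "pearson"),
                        node_ids = NULL, shrinkage = 0) {
  method <- match.arg(method)
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stopf("matrix must be square")
  if (max(abs(values - t(values))) > 1e-12) stopf("matrix must be symmetric")
  diag(values) <- 0
  if (max(abs(values)) > 1 + 1e-8)
    stopf("off-diagonal entries must lie in [-1, 1]")
  values[values > 1] <- 1
  values[values < -1] <- -1
  values <- (values + t(values)) / 2
  if (is.null(node_ids)) node_ids <- rownames(values) %||%
      sprintf("n%03d", seq_len(n))
  dimnames(values) <- list(node_ids, node_ids)
  structure(list(values = values, method = method, node_ids = node_ids,
                 shrinkage = shrinkage),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %d nodes, method = %s, shrinkage = %.4g\n",
              nrow(x$values), x$method, x$shrinkage))
  invisible(x)
}

#' Pearson full-correlation connectivity
#'
#' Standard product-moment correlations between all node pairs, with the
#' diagonal set to zero.
#'
#' @param ts a [ts_matrix()].
#' @return a `"pearson"` [conn_matrix()].
#' @export
pearson_matrix <- function(ts) {
  v <- rowMeans(ts$values^2) - rowMeans(ts$values)^2
  if (any(v < 1e-24))
    stopf("zero-variance node(s): %s",
          paste(ts$node_ids[v < 1e-24], collapse = ", "))
  R <- cor(t(ts$values))
  conn_matrix(R - diag(diag(R)), method = "pearson", node_ids = ts$node_ids)
}

# Schafer-Strimmer analytic shrinkage intensity for a correlation matrix
# shrunk toward the identity: lambda* = sum Var(r_ij) / sum r_ij^2 over
# off-diagonal pairs, clamped to [0, 1].
shrinkage_intensity <- function(ts) {
  X <- t(ts$values)
  n <- nrow(X)
  if (n < 4L) stopf("need more than 3 timepoints")
  Z <- scale(X)                     # standardized columns (sd uses n-1)
  W <- crossprod(Z) / n             # mean of w_ijt = z_i z_j
  S2 <- crossprod(Z^2) / n          # mean of w_ijt^2
  varw <- S2 - W^2                  # population variance of w over t
  var_r <- n / (n - 1)^3 * n * varw # n/(n-1)^3 * sum_t (w - wbar)^2
  r <- W * n / (n - 1)              # sample correlations
  off <- upper.tri(r)
  lam <- sum(var_r[off]) / sum(r[off]^2)
  min(1, max(0, lam))
}

#' Partial-correlation connectivity
#'
#' Pairwise partial correlation of every node pair conditioned on all
#' remaining nodes, obtained from the inverse of a shrinkage-regularized
#' correlation matrix: `rho_ij = -P_ij / sqrt(P_ii * P_jj)` where `P` is
#' the precision matrix. With many nodes and few volumes the sample
#' correlation matrix is near-singular, so by default the analytic
#' Ledoit-Wolf/Schafer-Strimmer intensity shrinks it toward the identity;
#' the intensity actually used is recorded on the result.
#'
#' @param ts a [ts_matrix()].
#' @param shrinkage `"auto"` (analytic intensity), or a fixed value in
#'   `[0, 1]`. At `shrinkage = 0` the raw correlation matrix must be
#'   invertible.
#' @return a `"partial"` [conn_matrix()] with the applied intensity in
#'   `$shrinkage`.
#' @export
partial_correlation_matrix <- function(ts, shrinkage = "auto") {
  if (n_time(ts) <= 3L) stopf("need more than 3 timepoints")
  v <- rowMeans(ts$values^2) - rowMeans(ts$values)^2
  if (any(v < 1e-24))
    stopf("zero-variance node(s): %s",
          paste(ts$node_ids[v < 1e-24], collapse = ", "))
  lam <- if (identical(shrinkage, "auto")) shrinkage_intensity(ts)
         else check_number(shrinkage, "shrinkage", lower = 0, upper = 1)
  R <- cor(t(ts$values))
  Rs <- (1 - lam) * R + lam * diag(nrow(R))
  P <- tryCatch(solve(Rs), error = function(e)
    stopf(paste("correlation matrix is not invertible at shrinkage = %g;",
                "enable shrinkage ('auto' or > 0)"), lam))
  D <- 1 / sqrt(diag(P))
  rho <- -P * outer(D, D)
  diag(rho) <- 0
  conn_matrix(rho, method = "partial", node_ids = ts$node_ids,
              shrinkage = lam)
}

#' Read / write connectivity matrices as delimited text
#'
#' Tab-separated matrix with a node-ID header row and column; a JSON
#' sidecar (`<path>.json`) records the method and shrinkage intensity.
#'
#' @param C a [conn_matrix()].
#' @param path file path.
#' @rdname conn_io
#' @export
write_conn_matrix <- function(C, path) {
  d <- data.frame(node_id = C$node_ids, C$values, check.names = FALSE)
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(method = C$method, shrinkage = C$shrinkage),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname conn_io
#' @export
read_conn_matrix <- function(path) {
  d <- read.csv(path, sep = "\t", check.names = FALSE)
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"))
  else list(method = "partial", shrinkage = 0)
  m <- as.matrix(d[, -1, drop = FALSE])
  m <- (m + t(m)) / 2   # guard against text round-trip asymmetry
  conn_matrix(m, method = meta$method, node_ids = d[[1]],
              shrinkage = meta$shrinkage)
}
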