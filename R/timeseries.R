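#' Regional BOLD time-series matrix
#'
#' Container for one scan session: a node x time matrix of BOLD signal
#' with its sampling interval (TR) and identifying metadata. All
#' preprocessing operations consume and return this class.
#'
#' @param values numeric node x time matrix (rows = nodes). All values
#'   must be finite and at least 3 volumes are required.
#' @param tr repetition time in seconds (sampling interval).
#' @param node_ids character vector of unique node labels; defaults to
#'   `"n001"`, `"n002"`, ...
#' @param subject_id,session optional identifying labels; `session` is
#'   conventionally `"pre"` or `"post"`.
#' @return an object of class `ts_matrix`.
#' @examples
#' ts <- ts_matrix(matrix(rnorm(40), 4, 10), tr = 2)
#' ts
#' @export
ts_matrix <- function(values, tr, node_ids = NULL, subject_id = NA_character_,
                      session = NA_character_) {
  values <- as.matrix(values)
  check_number(tr, "tr", lower = 1e-6)
  if (!is.numeric(values)) stopf("`values` must be numeric")
  if (ncol(values) < 3L) stopf("at least 3 volumes are required")
  if (!all(is.finite(values))) stopf("`values` contains non-finite entries")
  if (is.null(node_ids)) node_ids <- sprintf("n%03d", seq_len(nrow(values)))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != nrow(values))
    stopf("length(node_ids) [%d] != number of rows [%d]",
          length(node_ids), nrow(values))
  if (anyDuplicated(node_ids)) stopf("node_ids must be unique")
  rownames(values) <- node_ids
  structure(list(values = values, tr = tr, node_ids = node_ids,
                 subject_id = subject_id, session = session),
            class = "ts_matrix")
}

#' @export
print.ts_matrix <- function(x, ...) {
  cat(sprintf("<ts_matrix> %d nodes x %d volumes, TR = %gs", nrow(x$values),
              ncol(x$values), x$tr))
  if (!is.na(x$subject_id)) cat(sprintf(", subject %s", x$subject_id))
  if (!is.na(x$session)) cat(sprintf(" (%s)", x$session))
  cat("\n")
  invisible(x)
}

#' @export
dim.ts_matrix <- function(x) dim(x$values)

n_time <- function(ts) ncol(ts$values)
n_nodes <- function(ts) nrow(ts$values)

#' Read / write node time series as delimited text
#'
#' The on-disk format is tab-separated: one row per node, a `node_id`
#' first column, then one column per volume. TR is carried in a
#' `# tr: <seconds>` comment on the first line.
#'
#' @param path file path.
#' @param ts a [ts_matrix()].
#' @rdname timeseries_io
#' @return `read_timeseries()` returns a [ts_matrix()];
#'   `write_timeseries()` returns `path` invisibly.
#' @export
read_timeseries <- function(path) {
  header <- readLines(path, n = 1L)
  tr <- NA_real_
  if (grepl("^#\\s*tr:", header))
    tr <- as.numeric(sub("^#\\s*tr:\\s*", "", header))
  if (!is.finite(tr)) stopf("missing '# tr: <seconds>' header in %s", path)
  d <- read.csv(path, sep = "\t", comment.char = "#",
                stringsAsFactors = FALSE)
  ts_matrix(as.matrix(d[, -1, drop = FALSE]), tr = tr, node_ids = d[[1]])
}

#' @rdname timeseries_io
#' @export
write_timeseries <- function(ts, path) {
  d <- data.frame(node_id = ts$node_ids, ts$values, check.names = FALSE,
                  stringsAsFactors = FALSE)
  colnames(d) <- c("node_id", sprintf("t%04d", seq_len(n_time(ts))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr: %.10g", ts$tr), con)
  write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
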