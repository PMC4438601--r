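#' @useDynLib swnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor lm coef predict residuals sd var shapiro.test
#'   t.test p.adjust pf pt rnorm runif rbinom quantile setNames
#' @importFrom utils read.csv write.csv write.table head modifyList
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls never perturb user simulations.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Derive a reproducible sub-seed from a master seed and integer labels
#'
#' Deterministically mixes a master seed with stream labels (for example
#' subject index, session index, sparsity index) so that parallel or
#' partial reruns draw from the same independent RNG streams. The result
#' always lies in `[0, 2^31 - 2]`.
#'
#' @param seed master integer seed.
#' @param ... integer stream labels.
#' @return an integer seed.
#' @export
seed_stream <- function(seed, ...) {
  v <- c(seed, ...)
  h <- 0
  for (x in v) h <- (h * 1103515245 + as.numeric(x) %% 2147483647 + 12345) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("`%s` must lie in [%s, %s] (got %s)", name, lower, upper, x)
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != round(x)) stopf("`%s` must be an integer count", name)
  invisible(as.integer(x))
}
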