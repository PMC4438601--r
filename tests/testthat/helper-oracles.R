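# Brute-force reference implementations used to validate the graph
# metrics. Deliberately naive (explicit loops, exhaustive enumeration)
# and independent of the package's code paths.

oracle_clustering <- function(A) {
  n <- nrow(A)
  mx <- max(A)
  out <- numeric(n)
  if (mx == 0) return(out)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (a in seq_len(k - 1)) for (b in seq.int(a + 1, k)) {
      j <- nb[a]; l <- nb[b]
      if (A[j, l] > 0)
        s <- s + ((A[i, j] / mx) * (A[i, l] / mx) * (A[j, l] / mx))^(1 / 3)
    }
    out[i] <- 2 * s / (k * (k - 1))
  }
  out
}

# Floyd-Warshall in pure R on lengths 1/weight.
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- 1 / A
  D[A == 0] <- Inf
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_path_efficiency <- function(A) {
  D <- oracle_distances(A)
  d <- D[upper.tri(D)]
  fin <- is.finite(d)
  list(L = mean(d[fin]), Eglob = mean(ifelse(fin, 1 / d, 0)))
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) next
    out[i] <- oracle_path_efficiency(A[nb, nb, drop = FALSE])$Eglob
  }
  out
}

# All simple paths between s and t by depth-first search; returns list of
# integer vertex sequences.
all_simple_paths_bf <- function(A, s, t) {
  n <- nrow(A)
  paths <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (v in which(A[u, ] > 0)) if (!v %in% path) walk(c(path, v))
  }
  walk(s)
  paths
}

path_len <- function(A, path) {
  s <- 0
  for (e in seq_len(length(path) - 1L)) s <- s + 1 / A[path[e], path[e + 1L]]
  s
}

# Unnormalized node and edge betweenness by exhaustive shortest-path
# enumeration with fractional credit for ties.
oracle_betweenness <- function(A, tol = 1e-9) {
  n <- nrow(A)
  nodeb <- numeric(n)
  edgeb <- matrix(0, n, n)
  for (s in seq_len(n - 1)) for (t in seq.int(s + 1, n)) {
    paths <- all_simple_paths_bf(A, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, function(p) path_len(A, p), 1.0)
    sp <- paths[lens <= min(lens) + tol]
    for (p in sp) {
      if (length(p) > 2) {
        inner <- p[-c(1, length(p))]
        nodeb[inner] <- nodeb[inner] + 1 / length(sp)
      }
      for (e in seq_len(length(p) - 1L)) {
        i <- min(p[e], p[e + 1L]); j <- max(p[e], p[e + 1L])
        edgeb[i, j] <- edgeb[i, j] + 1 / length(sp)
      }
    }
  }
  list(node = nodeb, edge = edgeb)
}

# All set partitions of n elements as restricted growth strings.
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (c in seq_len(max(labels) + 1L)) grow(c(labels, c))
  }
  grow(1L)
  out
}

# Q of a partition by direct double loop over node pairs (independent of
# the package's community-sum formula).
oracle_q <- function(A, membership) {
  n <- nrow(A)
  m2 <- sum(A)
  k <- rowSums(A)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (membership[i] == membership[j])
      q <- q + A[i, j] / m2 - k[i] * k[j] / m2^2
  q
}

oracle_best_q <- function(A) {
  parts <- all_partitions(nrow(A))
  best <- -Inf
  for (p in parts) {
    q <- oracle_q(A, p)
    if (q > best) best <- q
  }
  best
}

# Seeded random connected weighted graph on n nodes.
random_connected_graph <- function(n, seed, p = 0.5, binary = FALSE) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    ut <- which(upper.tri(A))
    on <- runif(length(ut)) < p
    w <- if (binary) rep(1, sum(on)) else runif(sum(on), 0.2, 1)
    A[ut[on]] <- w
    A <- A + t(A)
    D <- oracle_distances(A)
    if (all(is.finite(D))) return(A)
  }
}
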