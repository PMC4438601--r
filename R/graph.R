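#' Proportional sparsity thresholding
#'
#' Retains the `round(S * n(n-1)/2)` strongest positive edges of a
#' connectivity matrix, keeping their weights; everything else becomes 0.
#' Edges are ranked by signed weight (so negative associations are
#' discarded first); set `rank = "absolute"` to rank by magnitude
#' instead, in which case retained weights are absolute values. Ties at
#' the cutoff are broken deterministically by lexicographic node-pair
#' order. If fewer positive edges exist than requested, all positive
#' edges are kept with a warning.
#'
#' @param C a [conn_matrix()] (or plain symmetric matrix).
#' @param S target sparsity (fraction of possible edges retained), in
#'   (0, 1).
#' @param rank `"signed"` (default) or `"absolute"`.
#' @return an object of class `wgraph`: nonnegative symmetric adjacency
#'   with fields `adjacency`, `S`, `density`, `n_edges`, `node_ids`.
#' @export
threshold_proportional <- function(C, S, rank = c("signed", "absolute")) {
  rank <- match.arg(rank)
  check_number(S, "S", lower = 1e-12, upper = 1 - 1e-12)
  W <- if (inherits(C, "conn_matrix")) C$values else as.matrix(C)
  node_ids <- if (inherits(C, "conn_matrix")) C$node_ids else
    rownames(W) %||% sprintf("n%03d", seq_len(nrow(W)))
  n <- nrow(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[upper.tri(W)]
  key <- if (rank == "absolute") abs(w) else w
  target <- round(S * n * (n - 1) / 2)
  pos <- which(key > 0)
  if (length(pos) < target) {
    warnf("only %d positive edge(s) available for target %d; keeping all",
          length(pos), target)
    keep <- pos
  } else {
    ord <- order(-key, ut[, 1], ut[, 2],   # strongest first, lexicographic ties
                 method = "radix")
    keep <- ord[seq_len(target)]
    keep <- keep[key[keep] > 0]
    if (length(keep) < target)
      warnf("only %d positive edge(s) available for target %d; keeping all",
            length(keep), target)
  }
  A <- matrix(0, n, n, dimnames = list(node_ids, node_ids))
  val <- if (rank == "absolute") abs(w[keep]) else w[keep]
  A[cbind(ut[keep, 1], ut[keep, 2])] <- val
  A <- A + t(A)
  wgraph(A, S = S)
}

#' Weighted graph container
#'
#' @param adjacency nonnegative symmetric matrix, zero diagonal.
#' @param S source sparsity threshold (or `NA` for graphs built
#'   directly).
#' @return an object of class `wgraph`.
#' @export
wgraph <- function(adjacency, S = NA_real_) {
  A <- as.matrix(adjacency)
  n <- nrow(A)
  if (ncol(A) != n) stopf("adjacency must be square")
  if (max(abs(A - t(A))) > 1e-12) stopf("adjacency must be symmetric")
  if (any(A < 0)) stopf("adjacency must be nonnegative")
  diag(A) <- 0
  m <- sum(A > 0) / 2
  ids <- rownames(A) %||% sprintf("n%03d", seq_len(n))
  dimnames(A) <- list(ids, ids)
  structure(list(adjacency = A, S = S, n_edges = m,
                 density = m / (n * (n - 1) / 2), node_ids = ids),
            class = "wgraph")
}

#' @export
print.wgraph <- function(x, ...) {
  cat(sprintf("<wgraph> %d nodes, %d edges (density %.3f%s)\n",
              nrow(x$adjacency), x$n_edges, x$density,
              if (is.na(x$S)) "" else sprintf(", S = %.2f", x$S)))
  invisible(x)
}

as_adj <- function(G) if (inherits(G, "wgraph")) G$adjacency else as.matrix(G)

as_igraph <- function(G) {
  igraph::graph_from_adjacency_matrix(as_adj(G), mode = "undirected",
                                      weighted = TRUE)
}

# All-pairs shortest path lengths on distance = 1/weight. Repeated
# Dijkstra on the (sparse) thresholded graph; the dense Floyd-Warshall
# kernel gives identical results and serves as an internal cross-check.
shortest_distances <- function(A) {
  cpp_dijkstra_all(A)
}

shortest_distances_fw <- function(A) {
  d <- 1 / A
  d[A == 0] <- Inf
  diag(d) <- 0
  cpp_floyd_warshall(d)
}

#' Weighted clustering coefficient (Onnela)
#'
#' Per-node weighted clustering using the geometric mean of triangle
#' weights, with weights normalized by the network maximum:
#' `C_i = sum_{jk} (w~_ij w~_ik w~_jk)^(1/3) / (k_i (k_i - 1))`. Nodes of
#' degree < 2 contribute 0. For binary graphs this reduces to the usual
#' triangle ratio.
#'
#' @param G a [wgraph()] or adjacency matrix.
#' @return list with `per_node` and `mean` (over all nodes, isolated
#'   included as 0).
#' @export
clustering_mean <- function(G) {
  A <- as_adj(G)
  n <- nrow(A)
  if (n == 0L || max(A) == 0) {
    z <- setNames(numeric(n), rownames(A))
    return(list(per_node = z, mean = 0))
  }
  ci <- cpp_onnela_clustering(A)
  list(per_node = setNames(as.numeric(ci), rownames(A)), mean = mean(ci))
}

#' Characteristic path length and global efficiency
#'
#' Shortest paths are computed on edge lengths `1/weight`. `L` is the
#' mean shortest-path length over connected node pairs (the number of
#' disconnected pairs is reported); `Eglob` is the mean of `1/d` over all
#' pairs with `1/Inf = 0`, so it degrades gracefully under
#' disconnection.
#'
#' @param G a [wgraph()] or adjacency matrix.
#' @return list with `L`, `Eglob`, `n_disconnected_pairs`.
#' @export
path_and_efficiency <- function(G) {
  A <- as_adj(G)
  n <- nrow(A)
  if (n < 2L) return(list(L = NaN, Eglob = 0, n_disconnected_pairs = 0))
  D <- shortest_distances(A)
  d <- D[upper.tri(D)]
  fin <- is.finite(d)
  L <- if (any(fin)) mean(d[fin]) else Inf
  inv <- ifelse(fin, 1 / d, 0)
  list(L = L, Eglob = mean(inv), n_disconnected_pairs = sum(!fin))
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced on its
#' neighbors; 0 for nodes of degree < 2.
#'
#' @param G a [wgraph()] or adjacency matrix.
#' @return list with `per_node` and `mean`.
#' @export
local_efficiency <- function(G) {
  A <- as_adj(G)
  n <- nrow(A)
  el <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2L) next
    el[i] <- path_and_efficiency(A[nb, nb, drop = FALSE])$Eglob
  }
  list(per_node = setNames(el, rownames(A)), mean = mean(el))
}

#' Newman weighted modularity of a given partition
#'
#' `Q = (1/2m) * sum_ij [A_ij - resolution * k_i k_j / 2m] delta(c_i, c_j)`
#' with node strengths `k` and total weight `2m = sum(A)`.
#'
#' @param G a [wgraph()] or adjacency matrix.
#' @param membership integer community label per node.
#' @param resolution resolution parameter (1 = standard).
#' @return scalar Q.
#' @export
newman_q <- function(G, membership, resolution = 1) {
  A <- as_adj(G)
  m2 <- sum(A)
  if (m2 <= 0) stopf("graph has no edge weight")
  membership <- as.integer(factor(membership))
  k <- rowSums(A)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    q <- q + sum(A[idx, idx]) / m2 - resolution * (sum(k[idx]) / m2)^2
  }
  q
}

# Greedy single-node relabelling sweep: move nodes between (existing or
# new) communities while any move increases Q. Used to polish the best
# Louvain restart.
refine_partition <- function(A, membership, resolution = 1, max_iter = 50L) {
  n <- nrow(A)
  membership <- as.integer(factor(membership))
  m2 <- sum(A)
  k <- rowSums(A)
  for (iter in seq_len(max_iter)) {
    improved <- FALSE
    for (i in seq_len(n)) {
      labs <- unique(c(membership[-i], max(membership) + 1L))
      best <- membership[i]
      q0 <- local_q_node(A, membership, i, membership[i], m2, k, resolution)
      bestgain <- 0
      for (c in labs) {
        if (c == membership[i]) next
        gain <- local_q_node(A, membership, i, c, m2, k, resolution) - q0
        if (gain > bestgain + 1e-13) {
          bestgain <- gain
          best <- c
        }
      }
      if (best != membership[i]) {
        membership[i] <- best
        membership <- as.integer(factor(membership))
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  membership
}

# Contribution to Q of node i if placed in community c (others fixed).
local_q_node <- function(A, membership, i, c, m2, k, resolution) {
  idx <- which(membership == c)
  idx <- idx[idx != i]
  (2 * sum(A[i, idx])) / m2 -
    resolution * (2 * k[i] * sum(k[idx]) + k[i]^2) / m2^2
}

#' Louvain community detection with restarts
#'
#' Louvain-style modularity optimization (multi-level local moving via
#' igraph) with `n_restarts` randomized restarts, followed by a greedy
#' single-node refinement sweep; the partition with the highest Newman Q
#' (recomputed by [newman_q()]) is returned.
#'
#' @param G a [wgraph()] or adjacency matrix.
#' @param resolution resolution parameter.
#' @param n_restarts randomized restarts.
#' @param seed integer seed.
#' @return list with `Q` and `partition` (integer labels).
#' @export
graph_modularity <- function(G, resolution = 1, n_restarts = 20L,
                             seed = NULL) {
  A <- as_adj(G)
  if (sum(A) <= 0) stopf("graph has no positive edge weight")
  g <- as_igraph(A)
  with_seed(seed, {
    bestQ <- -Inf
    bestp <- NULL
    for (r in seq_len(n_restarts)) {
      cl <- igraph::cluster_louvain(g, resolution = resolution)
      p <- refine_partition(A, igraph::membership(cl), resolution)
      q <- newman_q(A, p, resolution)
      if (q > bestQ + 1e-15) {
        bestQ <- q
        bestp <- p
      }
    }
    list(Q = bestQ, partition = bestp)
  })
}

#' Degree-preserving weighted null network
#'
#' Randomizes topology by double edge swaps (about `n_swaps_per_edge`
#' accepted-or-rejected attempts per edge), preserving each node's degree
#' exactly, then reassigns the original weight multiset to the surviving
#' edges in random order. Degree sequence and weight multiset are
#' invariant by construction. For graphs admitting no swap (complete
#' graphs), the topology is kept and only weights are shuffled, with a
#' warning.
#'
#' @param G a [wgraph()] or adjacency matrix.
#' @param n_swaps_per_edge swap attempts per edge.
#' @param seed integer seed.
#' @return a [wgraph()].
#' @export
randomize_graph <- function(G, n_swaps_per_edge = 10L, seed = NULL) {
  A <- as_adj(G)
  n <- nrow(A)
  ut <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  m <- nrow(ut)
  if (m < 2L) stopf("need at least 2 edges to randomize")
  w <- A[ut]
  with_seed(seed, {
    if (m == n * (n - 1) / 2) {
      warnf("complete graph admits no degree-preserving swap; shuffling weights only")
      edges <- ut
    } else {
      edges <- cpp_double_edge_swap(ut[, 1], ut[, 2], n, n_swaps_per_edge * m)
    }
    wperm <- sample(w)
    R <- matrix(0, n, n, dimnames = dimnames(A))
    R[edges] <- wperm
    R[edges[, 2:1, drop = FALSE]] <- wperm
    out <- wgraph(R, S = if (inherits(G, "wgraph")) G$S else NA_real_)
    out
  })
}

#' Global graph metrics with random-network normalization
#'
#' Computes the raw global metrics of a weighted graph (mean clustering
#' `C`, characteristic path length `L`, global efficiency `Eglob`, mean
#' local efficiency `Eloc`, modularity `Q`) and normalizes the
#' small-world attributes against `n_rand` degree-preserving random
#' networks: `gamma = C / <C_rand>`, `lambda = L / <L_rand>`,
#' `sigma = gamma / lambda`, and analogously `Eglob_norm` (and
#' `Eloc_norm` when `normalize_eloc = TRUE`; local efficiency requires an
#' induced-subgraph sweep per null, so it is off by default). Nulls with
#' zero clustering are excluded from the clustering null mean and
#' counted. Q is reported raw. Per-null values and the seed are retained
#' for audit.
#'
#' @param G a [wgraph()] or adjacency matrix.
#' @param n_rand number of random networks (study convention: 100).
#' @param seed integer seed for the null family.
#' @param normalize_eloc also normalize local efficiency (slow).
#' @param n_restarts Louvain restarts for Q.
#' @param n_swaps_per_edge swap attempts per edge for each null.
#' @return an object of class `global_metrics`: a list with the raw
#'   metrics, normalized `gamma`, `lambda`, `sigma`, `Eglob_norm`
#'   (`Eloc_norm` optional), `Q`, `partition`, `n_rand`, `seed`,
#'   `null_values` (data.frame), `n_null_zero_C`.
#' @export
normalized_metrics <- function(G, n_rand = 100L, seed = NULL,
                               normalize_eloc = FALSE, n_restarts = 20L,
                               n_swaps_per_edge = 10L) {
  A <- as_adj(G)
  C <- clustering_mean(A)$mean
  pe <- path_and_efficiency(A)
  El <- local_efficiency(A)$mean
  mod <- graph_modularity(A, n_restarts = n_restarts,
                          seed = if (is.null(seed)) NULL else
                            seed_stream(seed, 777L))
  nulls <- data.frame(C = numeric(n_rand), L = numeric(n_rand),
                      Eglob = numeric(n_rand),
                      Eloc = rep(NA_real_, n_rand))
  for (b in seq_len(n_rand)) {
    Rb <- randomize_graph(A, n_swaps_per_edge = n_swaps_per_edge,
                          seed = if (is.null(seed)) NULL else
                            seed_stream(seed, b))
    Ab <- Rb$adjacency
    nulls$C[b] <- clustering_mean(Ab)$mean
    peb <- path_and_efficiency(Ab)
    nulls$L[b] <- peb$L
    nulls$Eglob[b] <- peb$Eglob
    if (normalize_eloc) nulls$Eloc[b] <- local_efficiency(Ab)$mean
  }
  zeroC <- nulls$C <= 0
  Cbar <- mean(nulls$C[!zeroC])
  Lbar <- mean(nulls$L[is.finite(nulls$L)])
  gamma <- C / Cbar
  lambda <- pe$L / Lbar
  structure(list(C = C, L = pe$L, Eglob = pe$Eglob, Eloc = El,
                 Q = mod$Q, partition = mod$partition,
                 gamma = gamma, lambda = lambda, sigma = gamma / lambda,
                 Eglob_norm = pe$Eglob / mean(nulls$Eglob),
                 Eloc_norm = if (normalize_eloc) El / mean(nulls$Eloc)
                             else NA_real_,
                 n_rand = n_rand, seed = seed, null_values = nulls,
                 n_null_zero_C = sum(zeroC),
                 n_disconnected_pairs = pe$n_disconnected_pairs),
            class = "global_metrics")
}

#' @export
print.global_metrics <- function(x, ...) {
  cat(sprintf(paste0("<global_metrics> C=%.4f L=%.4f Eglob=%.4f ",
                     "Eloc=%.4f Q=%.4f\n  gamma=%.3f lambda=%.3f ",
                     "sigma=%.3f  (%d nulls)\n"),
              x$C, x$L, x$Eglob, x$Eloc, x$Q, x$gamma, x$lambda, x$sigma,
              x$n_rand))
  invisible(x)
}

#' Node- and edge-level metrics
#'
#' Degree (count of incident edges), Onnela clustering, local efficiency
#' and unnormalized weighted betweenness centrality per node
#' (Brandes-style, shortest paths on `1/weight`), plus edge betweenness
#' per edge.
#'
#' @param G a [wgraph()] or adjacency matrix.
#' @return list with `nodes` (data.frame: node_id, degree, clustering,
#'   local_efficiency, betweenness) and `edges` (data.frame: from, to,
#'   weight, betweenness).
#' @export
node_level_metrics <- function(G) {
  A <- as_adj(G)
  g <- as_igraph(A)
  wts <- igraph::E(g)$weight
  inv <- if (length(wts)) 1 / wts else numeric()
  btw <- igraph::betweenness(g, weights = inv, directed = FALSE)
  ebtw <- igraph::edge_betweenness(g, weights = inv, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  ids <- rownames(A) %||% sprintf("n%03d", seq_len(nrow(A)))
  list(nodes = data.frame(node_id = ids,
                          degree = rowSums(A > 0),
                          clustering = clustering_mean(A)$per_node,
                          local_efficiency = local_efficiency(A)$per_node,
                          betweenness = as.numeric(btw),
                          row.names = NULL),
       edges = data.frame(from = ids[el[, 1]], to = ids[el[, 2]],
                          weight = wts, betweenness = as.numeric(ebtw)))
}

#' Metric curves over the sparsity grid
#'
#' Thresholds a connectivity matrix at every sparsity in `grid`
#' (default 0.10 to 0.50 in steps of 0.05) and evaluates the requested
#' global metrics at each point, with one seeded null family per grid
#' point for the normalized metrics. Null RNG streams are derived from
#' `seed` and the grid index, so curves are reproducible point-by-point
#' under partial or parallel evaluation.
#'
#' @param C a [conn_matrix()].
#' @param grid sorted sparsity grid within (0, 1).
#' @param n_rand nulls per grid point (0 disables normalized metrics).
#' @param seed integer seed.
#' @param metrics character subset of `c("C", "L", "Eglob", "Eloc", "Q",
#'   "gamma", "lambda", "sigma", "Eglob_norm")`.
#' @param n_restarts Louvain restarts for Q.
#' @return an object of class `metric_curves`: data.frame with columns
#'   `metric`, `sparsity`, `value`; attributes carry grid, n_rand, seed.
#' @export
metric_curves <- function(C, grid = seq(0.1, 0.5, by = 0.05), n_rand = 100L,
                          seed = NULL,
                          metrics = c("C", "L", "Eglob", "Eloc", "Q",
                                      "gamma", "lambda", "sigma"),
                          n_restarts = 20L) {
  if (is.unsorted(grid, strictly = TRUE)) stopf("grid must be sorted, strictly increasing")
  if (any(grid <= 0 | grid >= 1)) stopf("grid values must lie in (0, 1)")
  known <- c("C", "L", "Eglob", "Eloc", "Q", "gamma", "lambda", "sigma",
             "Eglob_norm")
  bad <- setdiff(metrics, known)
  if (length(bad)) stopf("unknown metric(s): %s", paste(bad, collapse = ", "))
  need_null <- any(c("gamma", "lambda", "sigma", "Eglob_norm") %in% metrics)
  if (need_null && n_rand < 1L)
    stopf("normalized metrics require n_rand >= 1")
  rows <- vector("list", length(grid))
  for (si in seq_along(grid)) {
    S <- grid[si]
    G <- threshold_proportional(C, S)
    A <- G$adjacency
    val <- c()
    Cm <- NA_real_; pe <- NULL
    if (any(c("C", "gamma", "sigma") %in% metrics))
      Cm <- clustering_mean(A)$mean
    if (any(c("L", "Eglob", "lambda", "sigma", "Eglob_norm") %in% metrics))
      pe <- path_and_efficiency(A)
    if ("C" %in% metrics) val["C"] <- Cm
    if ("L" %in% metrics) val["L"] <- pe$L
    if ("Eglob" %in% metrics) val["Eglob"] <- pe$Eglob
    if ("Eloc" %in% metrics) val["Eloc"] <- local_efficiency(A)$mean
    if ("Q" %in% metrics)
      val["Q"] <- graph_modularity(A, n_restarts = n_restarts,
                                   seed = if (is.null(seed)) NULL else
                                     seed_stream(seed, si, 777L))$Q
    if (need_null) {
      nc <- nl <- ne <- numeric(n_rand)
      for (b in seq_len(n_rand)) {
        Ab <- randomize_graph(A, seed = if (is.null(seed)) NULL else
          seed_stream(seed, si, b))$adjacency
        if (any(c("gamma", "sigma") %in% metrics))
          nc[b] <- clustering_mean(Ab)$mean
        if (any(c("lambda", "sigma", "Eglob_norm") %in% metrics)) {
          peb <- path_and_efficiency(Ab)
          nl[b] <- peb$L
          ne[b] <- peb$Eglob
        }
      }
      gam <- Cm / mean(nc[nc > 0])
      lam <- pe$L / mean(nl[is.finite(nl)])
      if ("gamma" %in% metrics) val["gamma"] <- gam
      if ("lambda" %in% metrics) val["lambda"] <- lam
      if ("sigma" %in% metrics) val["sigma"] <- gam / lam
      if ("Eglob_norm" %in% metrics) val["Eglob_norm"] <- pe$Eglob / mean(ne)
    }
    rows[[si]] <- data.frame(metric = names(val), sparsity = S,
                             value = as.numeric(val), row.names = NULL)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("metric_curves", "data.frame"),
            grid = grid, n_rand = n_rand, seed = seed)
}

#' @export
plot.metric_curves <- function(x, metric = NULL, ...) {
  mets <- unique(x$metric)
  if (is.null(metric)) metric <- mets
  old <- graphics::par(mfrow = c(1, length(metric)))
  on.exit(graphics::par(old))
  for (m in metric) {
    d <- x[x$metric == m, ]
    plot(d$sparsity, d$value, type = "b", xlab = "sparsity S", ylab = m,
         main = m, ...)
  }
  invisible(x)
}
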