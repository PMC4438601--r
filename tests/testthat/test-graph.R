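triangle <- function() {
  A <- matrix(0, 3, 3)
  A[upper.tri(A)] <- 1
  A + t(A)
}

star <- function(n) {
  A <- matrix(0, n, n)
  A[1, 2:n] <- 1
  A + t(A)
}

test_that("proportional thresholding keeps the strongest positive edges", {
  set.seed(1)
  W <- matrix(0, 4, 4)
  W[upper.tri(W)] <- c(0.9, 0.5, 0.8, 0.2, 0.7, 0.1)
  W <- W + t(W)
  G <- threshold_proportional(W, 0.5)
  expect_equal(G$n_edges, 3)
  expect_setequal(G$adjacency[upper.tri(G$adjacency)][
    G$adjacency[upper.tri(G$adjacency)] > 0], c(0.9, 0.8, 0.7))

  # S covering all edges returns the positive part
  W2 <- W
  W2[1, 2] <- W2[2, 1] <- -0.3
  G2 <- threshold_proportional(W2, 0.8)
  expect_equal(sort(G2$adjacency[G2$adjacency > 0]),
               sort(W2[W2 > 0]))

  # negative edges are never selected even when requested count exceeds
  expect_warning(G3 <- threshold_proportional(W2, 0.95), "positive")
  expect_true(all(G3$adjacency >= 0))
})

test_that("ties at the cutoff break deterministically by node-pair order", {
  W <- matrix(0, 5, 5)
  W[upper.tri(W)] <- 0.5        # all tied
  W <- W + t(W)
  G1 <- threshold_proportional(W, 0.3)
  G2 <- threshold_proportional(W, 0.3)
  expect_identical(G1$adjacency, G2$adjacency)
  # explicit sort oracle: first round(0.3*10) = 3 pairs in (i,j) order
  ut <- which(upper.tri(W), arr.ind = TRUE)
  ord <- order(ut[, 1], ut[, 2])
  expected <- ut[ord[1:3], , drop = FALSE]
  got <- which(upper.tri(G1$adjacency) & G1$adjacency > 0, arr.ind = TRUE)
  expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE], expected,
               ignore_attr = TRUE)
})

test_that("clustering: analytic cases and brute-force agreement", {
  expect_equal(clustering_mean(triangle())$mean, 1)
  expect_equal(clustering_mean(star(6))$mean, 0)
  set.seed(11)
  for (s in 1:5) {
    A <- random_connected_graph(6, seed = 100 + s)
    expect_equal(unname(clustering_mean(A)$per_node), oracle_clustering(A),
                 tolerance = 1e-12)
  }
})

test_that("path length and efficiency: analytic cases and FW oracle", {
  K4 <- matrix(1, 4, 4) - diag(4)
  pe <- path_and_efficiency(K4)
  expect_equal(pe$L, 1)
  expect_equal(pe$Eglob, 1)

  P3 <- matrix(0, 3, 3)
  P3[1, 2] <- P3[2, 3] <- 1
  P3 <- P3 + t(P3)
  pe3 <- path_and_efficiency(P3)
  expect_equal(pe3$L, 4 / 3)
  expect_equal(pe3$Eglob, 5 / 6)

  for (s in 1:5) {
    A <- random_connected_graph(7, seed = 200 + s)
    o <- oracle_path_efficiency(A)
    got <- path_and_efficiency(A)
    expect_equal(got$L, o$L, tolerance = 1e-12)
    expect_equal(got$Eglob, o$Eglob, tolerance = 1e-12)
  }
})

test_that("local efficiency: analytic cases and induced-subgraph oracle", {
  expect_equal(local_efficiency(triangle())$mean, 1)
  expect_equal(local_efficiency(star(5))$mean, 0)
  for (s in 1:5) {
    A <- random_connected_graph(8, seed = 300 + s)
    expect_equal(unname(local_efficiency(A)$per_node),
                 oracle_local_efficiency(A), tolerance = 1e-12)
  }
})

test_that("modularity: analytic partitions and exhaustive optimum", {
  # two disconnected 4-cliques: optimal partition is the cliques, Q = 1/2
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1
  A[5:8, 5:8] <- 1
  diag(A) <- 0
  expect_equal(newman_q(A, rep(1:2, each = 4)), 0.5)
  # single community always scores 0
  expect_equal(newman_q(A, rep(1, 8)), 0)
  m <- graph_modularity(A, seed = 1)
  expect_equal(m$Q, 0.5)
  expect_equal(length(unique(m$partition)), 2)

  for (s in 1:5) {
    A6 <- random_connected_graph(6, seed = 400 + s)
    best <- oracle_best_q(A6)
    got <- graph_modularity(A6, seed = s)
    expect_equal(got$Q, best, tolerance = 1e-12)
  }
})

test_that("degree-preserving nulls keep degrees and weights exactly", {
  set.seed(5)
  for (s in 1:5) {
    A <- random_connected_graph(12, seed = 500 + s, p = 0.3)
    R <- randomize_graph(A, seed = s)
    expect_equal(rowSums(R$adjacency > 0), rowSums(A > 0),
                 ignore_attr = TRUE)
    expect_equal(sort(R$adjacency[upper.tri(R$adjacency) &
                                    R$adjacency > 0]),
                 sort(A[upper.tri(A) & A > 0]))
  }
  # ring lattice: randomization destroys local clustering
  rl <- as.matrix(igraph::as_adjacency_matrix(
    igraph::sample_smallworld(1, 30, 2, 0), sparse = TRUE))
  C0 <- clustering_mean(rl)$mean
  nullC <- vapply(1:50, function(b)
    clustering_mean(randomize_graph(rl, seed = b)$adjacency)$mean, 1.0)
  expect_lt(mean(nullC), C0)
  # complete graph: no swap possible, weights shuffled with warning
  K5 <- matrix(runif(25), 5, 5)
  K5 <- (K5 + t(K5)) / 2
  diag(K5) <- 0
  expect_warning(Rk <- randomize_graph(K5, seed = 1), "complete")
  expect_equal(sort(Rk$adjacency[upper.tri(Rk$adjacency)]),
               sort(K5[upper.tri(K5)]))
})

test_that("normalization produces the stubbed ratios and sane sigmas", {
  # gamma, lambda, sigma consistency against retained per-null values
  A <- random_connected_graph(20, seed = 600, p = 0.3)
  nm <- normalized_metrics(A, n_rand = 20, seed = 9)
  keep <- nm$null_values$C > 0
  expect_equal(nm$gamma, nm$C / mean(nm$null_values$C[keep]),
               tolerance = 1e-12)
  expect_equal(nm$lambda, nm$L / mean(nm$null_values$L), tolerance = 1e-12)
  expect_equal(nm$sigma, nm$gamma / nm$lambda, tolerance = 1e-12)
  # a random graph self-normalizes to sigma ~ 1; a lattice exceeds 1
  er <- as.matrix(igraph::as_adjacency_matrix(
    igraph::sample_gnp(60, 0.3), sparse = TRUE))
  expect_lt(abs(normalized_metrics(er, n_rand = 50, seed = 2)$sigma - 1),
            0.2)
  ws <- as.matrix(igraph::as_adjacency_matrix(
    igraph::sample_smallworld(1, 60, 3, 0.1), sparse = TRUE))
  expect_gt(normalized_metrics(ws, n_rand = 50, seed = 3)$sigma, 1)
})

test_that("betweenness: star analytics, bridge edges, exhaustive oracle", {
  nm <- node_level_metrics(star(5))
  expect_equal(nm$nodes$betweenness, c(6, 0, 0, 0, 0))
  expect_equal(nm$nodes$degree, c(4, 1, 1, 1, 1), ignore_attr = TRUE)

  # bridge between two triangles carries the most edge betweenness
  A <- matrix(0, 6, 6)
  A[1, 2] <- A[1, 3] <- A[2, 3] <- 1
  A[4, 5] <- A[4, 6] <- A[5, 6] <- 1
  A[3, 4] <- 1
  A <- A + t(A)
  nb <- node_level_metrics(A)
  bridge <- nb$edges$betweenness[(nb$edges$from == "n003" &
                                    nb$edges$to == "n004") |
                                   (nb$edges$from == "n004" &
                                      nb$edges$to == "n003")]
  expect_equal(bridge, max(nb$edges$betweenness))

  for (s in 1:4) {
    A <- random_connected_graph(7, seed = 700 + s, p = 0.45)
    o <- oracle_betweenness(A)
    got <- node_level_metrics(A)
    expect_equal(got$nodes$betweenness, o$node, tolerance = 1e-9)
    fi <- as.integer(sub("^n", "", got$edges$from))
    ti <- as.integer(sub("^n", "", got$edges$to))
    eb <- o$edge[cbind(pmin(fi, ti), pmax(fi, ti))]
    expect_equal(got$edges$betweenness, eb, tolerance = 1e-9)
  }
})

test_that("relabelling nodes permutes node metrics consistently", {
  A <- random_connected_graph(8, seed = 800)
  rownames(A) <- colnames(A) <- paste0("r", 1:8)
  perm <- sample(8)
  Ap <- A[perm, perm]
  m1 <- node_level_metrics(A)
  m2 <- node_level_metrics(Ap)
  expect_equal(m2$nodes$betweenness[match(m1$nodes$node_id,
                                          m2$nodes$node_id)],
               m1$nodes$betweenness, tolerance = 1e-10)
  expect_equal(m2$nodes$clustering[match(m1$nodes$node_id,
                                         m2$nodes$node_id)],
               m1$nodes$clustering, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("scale invariance: weight rescaling leaves normalized quantities", {
  A <- random_connected_graph(10, seed = 900, p = 0.4)
  expect_equal(clustering_mean(5 * A)$per_node,
               clustering_mean(A)$per_node, tolerance = 1e-12)
  expect_equal(rowSums((5 * A) > 0), rowSums(A > 0))
  m1 <- graph_modularity(A, seed = 4)
  m2 <- graph_modularity(5 * A, seed = 4)
  expect_equal(m1$partition, m2$partition)
  expect_equal(m1$Q, m2$Q, tolerance = 1e-12)
})

test_that("metric curves are pointwise deterministic and grid-stable", {
  set.seed(31)
  ts <- generate_modular_timeseries(30, 400, sort(rep_len(1:3, 30)),
                                    0.5, 0.1, seed = 77)
  C <- partial_correlation_matrix(ts)
  one <- metric_curves(C, grid = 0.3, n_rand = 0, metrics = c("C", "Eglob"))
  expect_equal(nrow(one), 2)
  coarse <- metric_curves(C, grid = c(0.2, 0.4), n_rand = 0,
                          metrics = c("C", "Eglob"))
  fine <- metric_curves(C, grid = c(0.2, 0.3, 0.4), n_rand = 0,
                        metrics = c("C", "Eglob"))
  shared <- merge(coarse, fine, by = c("metric", "sparsity"))
  expect_equal(shared$value.x, shared$value.y, tolerance = 1e-14)

  a <- metric_curves(C, grid = c(0.2, 0.4), n_rand = 3, seed = 5,
                     metrics = "sigma")
  b <- metric_curves(C, grid = c(0.2, 0.4), n_rand = 3, seed = 5,
                     metrics = "sigma")
  expect_identical(a$value, b$value)
  expect_error(metric_curves(C, grid = c(0.4, 0.2)), "sorted")
  expect_error(metric_curves(C, grid = c(0.2, 1.2)), "in \\(0, 1\\)")
})
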