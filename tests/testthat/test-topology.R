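path_graph <- function() {
  igraph::make_graph(~ a - b, b - c)
}

test_that("hand-computed metrics on a path and a triangle", {
  tp <- node_topology(path_graph())
  expect_equal(tp$degree, c(1, 2, 1))
  expect_equal(tp$betweenness_centrality, c(0, 1, 0))
  expect_equal(tp$eccentricity, c(2L, 1L, 2L))
  expect_equal(tp$clustering_coefficient, c(0, 0, 0))
  expect_equal(tp$average_shortest_path_length, c(1.5, 1, 1.5))
  expect_equal(tp$stress, c(0L, 1L, 0L))

  tri <- node_topology(igraph::make_full_graph(3))
  expect_equal(tri$clustering_coefficient, rep(1, 3))
  expect_equal(tri$betweenness_centrality, rep(0, 3))
  expect_equal(tri$average_shortest_path_length, rep(1, 3))
})

test_that("complete graphs K3..K8 hit their closed-form values", {
  for (n in 3:8) {
    tk <- node_topology(igraph::make_full_graph(n))
    expect_equal(tk$closeness_centrality, rep(1, n))
    expect_equal(tk$average_shortest_path_length, rep(1, n))
    expect_equal(tk$eccentricity, rep(1L, n))
    expect_equal(tk$neighborhood_connectivity, rep(n - 1, n))
    expect_equal(tk$stress, rep(0L, n))
  }
})

test_that("isolated nodes follow the pinned conventions", {
  g <- igraph::make_graph(~ a - b) + igraph::vertices("lonely")
  tp <- node_topology(g)
  iso <- tp[tp$node == "lonely", ]
  expect_equal(iso$degree, 0L)
  expect_equal(iso$closeness_centrality, 0)
  expect_equal(iso$eccentricity, 0L)
  expect_equal(iso$clustering_coefficient, 0)
  expect_equal(iso$average_shortest_path_length, 0)
  expect_equal(iso$radiality, 0)
})

test_that("all ten metrics equal the brute-force enumeration oracle", {
  for (s in 1:8) {
    A <- random_adjacency(18, p_edge = 0.14, seed = s)
    got <- node_topology(adjacency_to_graph(A))
    want <- oracle_topology(A)
    expect_equal(got$degree, want$degree)
    expect_equal(got$eccentricity, want$eccentricity)
    expect_equal(got$stress, want$stress)
    for (col in c("average_shortest_path_length", "betweenness_centrality",
                  "closeness_centrality", "clustering_coefficient",
                  "neighborhood_connectivity", "radiality",
                  "topological_coefficient")) {
      expect_equal(got[[col]], want[[col]], tolerance = 1e-9)
    }
  }
})

test_that("metrics are equivariant under node relabelling", {
  A <- random_adjacency(15, p_edge = 0.2, seed = 21)
  perm <- withr::with_seed(5, sample(15))
  t1 <- node_topology(adjacency_to_graph(A))
  t2 <- node_topology(adjacency_to_graph(A[perm, perm]))
  # node i of graph 1 is row which(perm == i) of graph 2
  reord <- match(seq_len(15), perm)
  for (col in setdiff(names(t1), "node")) {
    expect_equal(t2[[col]][reord], t1[[col]], tolerance = 1e-12)
  }
})

test_that("directed graphs and self-loops are rejected", {
  expect_error(node_topology(igraph::make_graph(c(1, 2), directed = TRUE)),
               "undirected")
  g <- igraph::make_graph(c(1, 2, 2, 2), directed = FALSE)
  expect_error(node_topology(g), "Self-loops")
})

test_that("identical networks have coincident topology-PCA centroids", {
  A <- random_adjacency(20, p_edge = 0.15, seed = 3)
  tab <- node_topology(adjacency_to_graph(A))
  suppressWarnings(pca <- topology_pca(list(net1 = tab, net2 = tab)))
  expect_equal(pca$centroid_distances$distance, 0, tolerance = 1e-9)
})

test_that("topology PCA separates a sparse path-like from a dense network", {
  sparse <- node_topology(igraph::make_ring(20))
  dense <- node_topology(adjacency_to_graph(random_adjacency(20, 0.5, seed = 6)))
  suppressWarnings(pca <- topology_pca(list(sparse = sparse, dense = dense)))
  expect_gt(pca$centroid_distances$distance, 0.5)
  expect_gt(nrow(pca$loadings), 2)
})

test_that("PCA scores reproduce an independent eigendecomposition", {
  t1 <- node_topology(adjacency_to_graph(random_adjacency(25, 0.2, seed = 8)))
  t2 <- node_topology(adjacency_to_graph(random_adjacency(25, 0.3, seed = 9)))
  pca <- suppressWarnings(topology_pca(list(a = t1, b = t2)))
  stacked <- rbind(as.matrix(t1[-1]), as.matrix(t2[-1]))
  keep <- apply(stacked, 2, sd) > 0
  z <- scale(stacked[, keep])
  ev <- eigen(cov(z))
  ref <- z %*% ev$vectors[, 1:2]
  # align signs before comparing
  for (j in 1:2) {
    got <- pca$scores[[paste0("PC", j)]]
    if (sum(got * ref[, j]) < 0) ref[, j] <- -ref[, j]
    expect_equal(got, unname(ref[, j]), tolerance = 1e-9)
  }
})

test_that("per-network aggregation gives one row per network", {
  t1 <- node_topology(adjacency_to_graph(random_adjacency(12, 0.3, seed = 1)))
  t2 <- node_topology(adjacency_to_graph(random_adjacency(12, 0.4, seed = 2)))
  t3 <- node_topology(adjacency_to_graph(random_adjacency(12, 0.5, seed = 3)))
  pca <- suppressWarnings(
    topology_pca(list(a = t1, b = t2, c = t3), aggregate = "network")
  )
  expect_equal(nrow(pca$scores), 3)
})
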