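#' NetworkAnalyzer-style node topology metrics
#'
#' Computes the ten standard per-node metrics of an undirected, unweighted
#' simple graph: degree, average shortest path length, betweenness
#' centrality (normalised by `(n_c - 1)(n_c - 2) / 2` within each
#' connected component of size `n_c`), closeness centrality (reciprocal of
#' the mean distance to reachable nodes), clustering coefficient,
#' eccentricity (largest finite distance), neighborhood connectivity
#' (mean degree of the neighbours), radiality
#' (`(diam_c + 1 - aspl) / diam_c` with `diam_c` the component diameter),
#' stress (number of shortest paths passing through the node) and
#' topological coefficient (mean shared-neighbour overlap
#' `J(v, m) / k_v` over all nodes `m` sharing at least one neighbour with
#' `v`, where `J` counts shared neighbours plus one if `v` and `m` are
#' adjacent).
#'
#' Isolated nodes get degree, clustering, eccentricity, closeness, average
#' shortest path length and radiality 0; nodes with fewer than two
#' neighbours get topological coefficient 0.
#'
#' @param net An `assoc_network` (see [build_network()]) or an undirected
#'   igraph graph.
#' @return A tibble with a `node` column and one column per metric.
#' @export
node_topology <- function(net) {
  g <- if (inherits(net, "assoc_network")) as_igraph(net) else net
  if (!igraph::is_igraph(g)) abort("`net` must be an assoc_network or igraph graph.")
  if (igraph::is_directed(g)) abort("Graph must be undirected.")
  if (any(igraph::which_loop(g))) abort("Self-loops are not allowed.")
  if (any(igraph::count_multiple(g) > 1)) abort("Multi-edges are not allowed.")
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name %||% as.character(seq_len(n))
  deg <- unname(igraph::degree(g))
  comp <- igraph::components(g)
  comp_size <- comp$csize[comp$membership]
  D <- igraph::distances(g, weights = NA)

  finite_mean <- function(row, self) {
    d <- row[-self]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else mean(d)
  }
  aspl <- vapply(seq_len(n), function(v) finite_mean(D[v, ], v), 0)
  closeness <- ifelse(aspl > 0, 1 / aspl, 0)
  ecc <- vapply(seq_len(n), function(v) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else max(d)
  }, 0)

  btw_raw <- unname(igraph::betweenness(g, directed = FALSE, weights = NA))
  denom <- (comp_size - 1) * (comp_size - 2) / 2
  btw <- ifelse(denom > 0, btw_raw / denom, 0)

  clust <- igraph::transitivity(g, type = "local", isolates = "zero",
                                vids = igraph::V(g))
  clust[is.nan(clust)] <- 0

  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  nbr_conn <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) == 0) 0 else mean(deg[nb])
  }, 0)

  diam_c <- vapply(seq_len(n), function(v) {
    members <- which(comp$membership == comp$membership[v])
    if (length(members) < 2) 0 else max(D[members, members][is.finite(D[members, members])])
  }, 0)
  radiality <- ifelse(diam_c > 0, (diam_c + 1 - aspl) / diam_c, 0)

  stress <- stress_centrality(g)

  S <- A %*% A # shared-neighbour counts
  topo_coef <- vapply(seq_len(n), function(v) {
    if (deg[v] < 2) return(0)
    m <- which(S[v, ] > 0 & seq_len(n) != v)
    if (length(m) == 0) return(0)
    mean(S[v, m] + A[v, m]) / deg[v]
  }, 0)

  tibble::tibble(
    node = nodes,
    degree = as.integer(deg),
    average_shortest_path_length = aspl,
    betweenness_centrality = btw,
    closeness_centrality = unname(closeness),
    clustering_coefficient = as.numeric(clust),
    eccentricity = as.integer(ecc),
    neighborhood_connectivity = nbr_conn,
    radiality = unname(radiality),
    stress = as.integer(round(stress)),
    topological_coefficient = topo_coef
  )
}

# Stress centrality: the number of shortest paths between all unordered
# node pairs (s, t) that pass through v as an interior node. Uses
# per-source BFS shortest-path counts sigma and the composition rule
# sigma_st(v) = sigma_sv * sigma_vt when d_sv + d_vt = d_st.
stress_centrality <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0) return(numeric(0))
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  D <- igraph::distances(g, weights = NA)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sig <- numeric(n)
    sig[s] <- 1
    ds <- D[s, ]
    maxd <- max(ds[is.finite(ds)])
    if (maxd >= 1) {
      for (d in seq_len(maxd)) {
        for (w in which(ds == d)) {
          pred <- adj[[w]][ds[adj[[w]]] == d - 1]
          sig[w] <- sum(sig[pred])
        }
      }
    }
    sigma[s, ] <- sig
  }
  vapply(seq_len(n), function(v) {
    total <- 0
    dv <- D[, v]
    reach <- which(is.finite(dv) & seq_len(n) != v)
    for (s in reach) {
      for (t in reach) {
        if (t <= s) next
        if (is.finite(D[s, t]) && D[s, v] + D[v, t] == D[s, t]) {
          total <- total + sigma[s, v] * sigma[v, t]
        }
      }
    }
    total
  }, 0)
}

#' PCA comparison of network topologies
#'
#' Stacks the per-node metric tables of several networks into one
#' (network, node) x metric matrix, unit-variance scales the columns, and
#' runs a two-component PCA. Networks with similar topology overlap in
#' the score plane; the distance between network centroids is returned as
#' a scalar separation summary. `aggregate = "network"` instead reduces
#' each network to its vector of metric means before the PCA (one point
#' per network; at least as many networks as interpretable components are
#' then needed).
#'
#' @param tables Named list of [node_topology()] tibbles, one per network.
#' @param aggregate `"nodes"` (default) or `"network"`.
#' @return A `topology_pca` object: `scores` (tibble: network, node, PC1,
#'   PC2), `loadings` (tibble: metric, PC1, PC2), `centroids`,
#'   `centroid_distances` (tibble: network_a, network_b, distance),
#'   `var_explained`, `dropped` (zero-variance metrics).
#' @export
topology_pca <- function(tables, aggregate = c("nodes", "network")) {
  aggregate <- match.arg(aggregate)
  if (length(tables) < 2) abort("Need at least 2 networks.")
  if (is.null(names(tables)) || any(names(tables) == "")) {
    abort("`tables` must be a named list (one name per network).")
  }
  stacked <- dplyr::bind_rows(
    lapply(names(tables), function(nm) {
      dplyr::mutate(tables[[nm]], network = nm, .before = 1)
    })
  )
  if (aggregate == "network") {
    stacked <- stacked |>
      dplyr::group_by(.data$network) |>
      dplyr::summarise(dplyr::across(-"node", mean), .groups = "drop") |>
      dplyr::mutate(node = .data$network, .after = "network")
  }
  metrics <- setdiff(names(stacked), c("network", "node"))
  m <- as.matrix(stacked[, metrics])
  sds <- apply(m, 2, sd)
  dropped <- metrics[sds == 0]
  if (length(dropped) > 0) {
    warn(paste0("Dropping zero-variance metric(s): ", paste(dropped, collapse = ", ")))
    m <- m[, sds > 0, drop = FALSE]
  }
  if (ncol(m) < 2) abort("Fewer than 2 informative metrics; PCA impossible.")
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  scores <- tibble::tibble(
    network = stacked$network, node = stacked$node,
    PC1 = pc$x[, 1], PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0
  )
  loadings <- tibble::tibble(
    metric = rownames(pc$rotation),
    PC1 = pc$rotation[, 1],
    PC2 = if (ncol(pc$rotation) >= 2) pc$rotation[, 2] else 0
  )
  centroids <- scores |>
    dplyr::group_by(.data$network) |>
    dplyr::summarise(PC1 = mean(.data$PC1), PC2 = mean(.data$PC2), .groups = "drop")
  pairs <- utils::combn(centroids$network, 2)
  centroid_distances <- tibble::tibble(
    network_a = pairs[1, ], network_b = pairs[2, ],
    distance = apply(pairs, 2, function(p) {
      a <- centroids[centroids$network == p[1], c("PC1", "PC2")]
      b <- centroids[centroids$network == p[2], c("PC1", "PC2")]
      sqrt(sum((unlist(a) - unlist(b))^2))
    })
  )
  structure(
    list(
      scores = scores, loadings = loadings, centroids = centroids,
      centroid_distances = centroid_distances,
      var_explained = pc$sdev^2 / sum(pc$sdev^2),
      dropped = dropped, aggregate = aggregate
    ),
    class = "topology_pca"
  )
}

#' @export
print.topology_pca <- function(x, ...) {
  cat("<topology_pca> ", length(unique(x$scores$network)), " networks, ",
      nrow(x$scores), " rows; PC1+PC2 explain ",
      round(100 * sum(x$var_explained[1:2])), "%\n", sep = "")
  invisible(x)
}

#' @rdname topology_pca
#' @param x A `topology_pca`.
#' @param ... Unused.
#' @method tidy topology_pca
#' @export
tidy.topology_pca <- function(x, ...) x$scores
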