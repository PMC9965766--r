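# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths (and igraph) so that agreement is a
# genuine cross-check, not a tautology.

# Benjamini-Hochberg by direct definition: q_i = min_{j: p_(j) >= p_i over
# ranks >= rank(i)} min(1, p_(j) * m / j), computed without the cummin trick.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    candidates <- vapply(rank_i:m, function(j) p[ord[j]] * m / j, 0)
    q[i] <- min(1, min(candidates))
  }
  q
}

# Hypergeometric upper tail P(X >= k) by combinatorial enumeration.
hyper_oracle <- function(k, N, K, n) {
  total <- choose(N, n)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / total
}

# Pure-R PCLRC mirror of the documented definition, built on stats::cor.
r_clr <- function(M) {
  p <- nrow(M)
  out <- matrix(0, p, p)
  mu <- numeric(p); sdv <- numeric(p)
  for (i in seq_len(p)) {
    row <- M[i, -i]
    mu[i] <- mean(row)
    sdv[i] <- if (p > 2) sd(row) else 0
  }
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i < j) {
      zi <- if (sdv[i] > 0) max(0, (M[i, j] - mu[i]) / sdv[i]) else 0
      zj <- if (sdv[j] > 0) max(0, (M[j, i] - mu[j]) / sdv[j]) else 0
      out[i, j] <- out[j, i] <- sqrt(zi^2 + zj^2)
    }
  }
  out
}

r_keep_mask <- function(clr, retention) {
  vals <- clr[upper.tri(clr)]
  vals <- vals[vals > 0]
  mask <- matrix(0, nrow(clr), ncol(clr))
  if (length(vals) == 0) return(mask)
  keep <- min(length(vals), ceiling(retention * length(vals)))
  if (keep == 0) return(mask)
  cutoff <- sort(vals, decreasing = TRUE)[keep]
  sel <- clr >= cutoff & clr > 0 & upper.tri(clr)
  mask[sel] <- 1
  mask + t(mask)
}

r_pclrc <- function(x, n_iterations, subsample_fraction, retention, seed) {
  n <- nrow(x)
  ss <- floor(subsample_fraction * n)
  subsets <- withr::with_seed(seed, {
    vapply(seq_len(n_iterations), function(i) sample.int(n, ss), integer(ss))
  })
  counts <- matrix(0, ncol(x), ncol(x))
  for (it in seq_len(n_iterations)) {
    r <- suppressWarnings(cor(x[subsets[, it], ], method = "spearman"))
    r[is.na(r)] <- 0
    m <- r^2
    diag(m) <- 0
    counts <- counts + r_keep_mask(r_clr(m), retention)
  }
  counts / n_iterations
}

# ---- brute-force graph topology oracle --------------------------------

# Floyd-Warshall distances on an adjacency matrix.
fw_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# Enumerate every shortest path between s and t as explicit node vectors,
# by backtracking over the predecessor structure implied by the distances.
enumerate_shortest_paths <- function(A, D, s, t) {
  if (!is.finite(D[s, t])) return(list())
  if (s == t) return(list(s))
  extend <- function(path) {
    last <- path[length(path)]
    if (last == t) return(list(path))
    nexts <- which(A[last, ] > 0 & D[, t] == D[last, t] - 1)
    out <- list()
    for (w in nexts) out <- c(out, extend(c(path, w)))
    out
  }
  extend(s)
}

oracle_topology <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  D <- fw_distances(A)
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (v in seq_len(n)) {
    if (is.na(comp[v])) {
      cid <- cid + 1
      comp[is.finite(D[v, ])] <- cid
    }
  }
  aspl <- closeness <- ecc <- rad <- btw <- stress <- clust <- nbr <- tc <- numeric(n)
  # path enumeration once per unordered pair
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || !is.finite(D[s, t])) next
    paths <- enumerate_shortest_paths(A, D, s, t)
    npath <- length(paths)
    interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(interior) > 0) {
      counts <- table(interior)
      idx <- as.integer(names(counts))
      stress[idx] <- stress[idx] + as.numeric(counts)
      btw[idx] <- btw[idx] + as.numeric(counts) / npath
    }
  }
  for (v in seq_len(n)) {
    reach <- which(is.finite(D[v, ]) & seq_len(n) != v)
    aspl[v] <- if (length(reach) == 0) 0 else mean(D[v, reach])
    closeness[v] <- if (aspl[v] > 0) 1 / aspl[v] else 0
    ecc[v] <- if (length(reach) == 0) 0 else max(D[v, reach])
    members <- which(comp == comp[v])
    diam <- if (length(members) < 2) 0 else {
      max(D[members, members][is.finite(D[members, members])])
    }
    rad[v] <- if (diam > 0) (diam + 1 - aspl[v]) / diam else 0
    nc <- length(members)
    btw[v] <- if (nc > 2) btw[v] / (((nc - 1) * (nc - 2)) / 2) else 0
    nb <- which(A[v, ] > 0)
    nbr[v] <- if (length(nb) == 0) 0 else mean(deg[nb])
    k <- deg[v]
    clust[v] <- if (k < 2) 0 else {
      links <- sum(A[nb, nb]) / 2
      2 * links / (k * (k - 1))
    }
    if (k >= 2) {
      shares <- vapply(seq_len(n), function(m) {
        if (m == v) return(NA_real_)
        shared <- sum(A[v, ] > 0 & A[m, ] > 0)
        if (shared == 0) return(NA_real_)
        shared + (A[v, m] > 0)
      }, 0)
      shares <- shares[!is.na(shares)]
      tc[v] <- if (length(shares) == 0) 0 else mean(shares) / k
    }
  }
  tibble::tibble(
    degree = as.integer(deg),
    average_shortest_path_length = aspl,
    betweenness_centrality = btw,
    closeness_centrality = closeness,
    clustering_coefficient = clust,
    eccentricity = as.integer(ecc),
    neighborhood_connectivity = nbr,
    radiality = rad,
    stress = as.integer(round(stress)),
    topological_coefficient = tc
  )
}

# Random simple undirected graph as adjacency matrix.
random_adjacency <- function(n, p_edge, seed) {
  withr::with_seed(seed, {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    A[up] <- rbinom(length(up), 1, p_edge)
    A + t(A)
  })
}

adjacency_to_graph <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- sprintf("n%02d", seq_len(nrow(A)))
  g
}
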