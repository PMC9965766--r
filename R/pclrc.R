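#' Spearman correlation matrix of an abundance table
#'
#' Pairwise Spearman rank correlation (average ranks for ties) between all
#' metabolites. Constant metabolites get correlation 0 with a warning
#' rather than `NA`.
#'
#' @inheritParams as_abundance
#' @return Symmetric matrix with unit diagonal, metabolite names on both
#'   dimensions.
#' @export
spearman_matrix <- function(data) {
  x <- abundance_matrix(as_abundance(data, require_nonnegative = FALSE))
  if (nrow(x) < 4) abort("Need at least 4 samples for a correlation matrix.")
  if (anyNA(x)) abort("Missing values present; run impute_missing() first.")
  const <- apply(x, 2, function(v) diff(range(v)) == 0)
  if (any(const)) {
    warn(paste0("Constant metabolite(s), correlations set to 0: ",
                paste(colnames(x)[const], collapse = ", ")))
  }
  r <- cpp_spearman(x)
  dimnames(r) <- list(colnames(x), colnames(x))
  r
}

#' Context-likelihood-of-relatedness background filter
#'
#' Rescores each entry of a symmetric non-negative association matrix
#' against the background of its two incident rows:
#' `z_i|j = (M_ij - mean(M_i.)) / sd(M_i.)` (row statistics exclude the
#' diagonal), and the CLR score of edge (i, j) combines the two one-sided
#' z-scores as `sqrt(max(0, z_i|j)^2 + max(0, z_j|i)^2)`. An edge scores
#' high only if it stands out from the typical association level of both
#' of its endpoints.
#'
#' @param M Symmetric non-negative matrix (e.g. squared Spearman
#'   correlations with zero diagonal).
#' @return Symmetric matrix of CLR scores with zero diagonal.
#' @export
clr_filter <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) abort("`M` must be a square matrix.")
  if (any(M < 0)) abort("`M` must be non-negative.")
  if (max(abs(M - t(M))) > 1e-8) abort("`M` must be symmetric.")
  out <- cpp_clr(M)
  dimnames(out) <- dimnames(M)
  out
}

#' PCLRC inference of an edge-probability matrix
#'
#' Probabilistic Context Likelihood of Relatedness on Correlation: for each
#' of `n_iterations` rounds, a fraction of the samples is drawn without
#' replacement, the Spearman correlation matrix of the subsample is
#' squared and passed through the CLR filter, and the top
#' `retention_quantile` fraction of the positive CLR scores is marked as
#' "kept". The probability `p_ij` of an edge is the fraction of rounds in
#' which it was kept; the full-data Spearman matrix `R` supplies the edge
#' weight and its sign.
#'
#' @inheritParams as_abundance
#' @param n_iterations Number of subsampling rounds (default 1000).
#' @param subsample_fraction Fraction of samples drawn per round without
#'   replacement (default 0.75).
#' @param retention_quantile Fraction of positive CLR scores retained per
#'   round (default 0.30).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return A `pclrc_result`: list with `P` (edge probabilities, zero
#'   diagonal), `R` (full-data Spearman matrix) and `settings`.
#' @seealso [build_network()], [connectivity()]
#' @export
pclrc_infer <- function(data, n_iterations = 1000, subsample_fraction = 0.75,
                        retention_quantile = 0.30, seed = 1L) {
  data <- as_abundance(data, require_nonnegative = FALSE)
  x <- abundance_matrix(data)
  if (anyNA(x)) abort("Missing values present; run impute_missing() first.")
  n <- nrow(x)
  if (n < 20) abort("PCLRC needs at least 20 samples.")
  if (n < 40) warn("Fewer than 40 samples; edge probabilities will be noisy.")
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    abort("`subsample_fraction` must lie in (0, 1].")
  }
  ss <- floor(subsample_fraction * n)
  if (ss < 5) abort("Subsample smaller than 5 samples.")
  subsets <- with_seed(seed, {
    vapply(seq_len(n_iterations), function(i) sample.int(n, ss), integer(ss))
  })
  counts <- cpp_pclrc_counts(x, matrix(as.integer(subsets), nrow = ss), retention_quantile)
  P <- counts / n_iterations
  dimnames(P) <- list(colnames(x), colnames(x))
  R <- cpp_spearman(x)
  dimnames(R) <- dimnames(P)
  structure(
    list(
      P = P, R = R,
      settings = list(
        n_iterations = n_iterations, subsample_fraction = subsample_fraction,
        retention_quantile = retention_quantile, seed = as.integer(seed),
        n_samples = n
      )
    ),
    class = "pclrc_result"
  )
}

#' @export
print.pclrc_result <- function(x, ...) {
  cat("<pclrc_result> ", ncol(x$P), " metabolites, ",
      x$settings$n_iterations, " iterations on ", x$settings$n_samples,
      " samples\n", sep = "")
  invisible(x)
}

#' Per-edge tidy view of a PCLRC result
#'
#' @param x A `pclrc_result`.
#' @param ... Unused.
#' @return Tibble with one row per metabolite pair: `from`, `to`,
#'   `probability`, `r`.
#' @method tidy pclrc_result
#' @export
tidy.pclrc_result <- function(x, ...) {
  p <- ncol(x$P)
  idx <- which(upper.tri(x$P), arr.ind = TRUE)
  tibble::tibble(
    from = rownames(x$P)[idx[, 1]],
    to = colnames(x$P)[idx[, 2]],
    probability = x$P[idx],
    r = x$R[idx]
  )
}

new_assoc_network <- function(nodes, edges, p_min, r_min) {
  structure(
    list(nodes = nodes, edges = edges, p_min = p_min, r_min = r_min),
    class = "assoc_network"
  )
}

node_connectivity_from_edges <- function(names, edges) {
  conn <- setNames(rep(0, length(names)), names)
  if (nrow(edges) > 0) {
    w <- abs(edges$weight) * edges$probability
    for (i in seq_len(nrow(edges))) {
      conn[edges$from[i]] <- conn[edges$from[i]] + w[i]
      conn[edges$to[i]] <- conn[edges$to[i]] + w[i]
    }
  }
  unname(conn[names])
}

#' Threshold a PCLRC result into an association network
#'
#' Keeps the edges whose probability reaches `p_min` and whose full-data
#' Spearman correlation has magnitude at least `r_min`; all metabolites
#' remain as nodes (isolated if nothing passes). Edge weight is the signed
#' correlation; each node carries a `connectivity` attribute
#' (sum of `probability * |r|` over its retained edges).
#'
#' @param res A [pclrc_infer()] result.
#' @param p_min Minimum edge probability (default 0.95).
#' @param r_min Minimum absolute Spearman correlation (default 0.6).
#' @return An `assoc_network`: list with `nodes` (tibble: name,
#'   connectivity), `edges` (tibble: from, to, weight, probability) and the
#'   thresholds used.
#' @export
build_network <- function(res, p_min = 0.95, r_min = 0.6) {
  stopifnot(inherits(res, "pclrc_result"))
  keep <- upper.tri(res$P) & res$P >= p_min & abs(res$R) >= r_min
  idx <- which(keep, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = rownames(res$P)[idx[, 1]],
    to = colnames(res$P)[idx[, 2]],
    weight = res$R[keep],
    probability = res$P[keep]
  )
  nodes <- tibble::tibble(name = colnames(res$P))
  nodes$connectivity <- node_connectivity_from_edges(nodes$name, edges)
  new_assoc_network(nodes, edges, p_min, r_min)
}

#' @export
print.assoc_network <- function(x, ...) {
  cat("<assoc_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (p >= ", format(x$p_min), ", |r| >= ", format(x$r_min), ")\n",
      sep = "")
  invisible(x)
}

#' Convert an association network to an igraph graph
#'
#' @param net An `assoc_network`.
#' @return An undirected igraph graph with `connectivity` vertex attribute
#'   and `weight`/`probability` edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  igraph::graph_from_data_frame(
    as.data.frame(net$edges),
    directed = FALSE,
    vertices = as.data.frame(net$nodes)
  )
}
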