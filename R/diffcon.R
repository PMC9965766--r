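#' Node connectivity of a PCLRC result
#'
#' The connectivity of metabolite i is the probability-weighted absolute
#' association strength `C_i = sum_j p_ij * |r_ij|` over all other
#' metabolites. This uses the full probability and correlation matrices,
#' not a thresholded graph, so it has no threshold cliff; it reduces to a
#' weighted node degree when `P` is binary. `statistic = "thresholded_degree"`
#' instead counts edges with `p_ij >= p_min` and `|r_ij| >= r_min`.
#'
#' @param res A [pclrc_infer()] result.
#' @param statistic `"weighted_strength"` (default) or
#'   `"thresholded_degree"`.
#' @param p_min,r_min Thresholds for `"thresholded_degree"`.
#' @return Tibble with columns `metabolite`, `connectivity`.
#' @export
connectivity <- function(res, statistic = c("weighted_strength", "thresholded_degree"),
                         p_min = 0.95, r_min = 0.6) {
  stopifnot(inherits(res, "pclrc_result"))
  statistic <- match.arg(statistic)
  C <- connectivity_vec(res$P, res$R, statistic, p_min, r_min)
  tibble::tibble(metabolite = colnames(res$P), connectivity = C)
}

connectivity_vec <- function(P, R, statistic = "weighted_strength",
                             p_min = 0.95, r_min = 0.6) {
  if (statistic == "weighted_strength") {
    unname(rowSums(P * abs(R)) - diag(P) * abs(diag(R)))
  } else {
    A <- (P >= p_min) & (abs(R) >= r_min)
    diag(A) <- FALSE
    unname(rowSums(A))
  }
}

#' Differential connectivity between two group networks
#'
#' Infers a PCLRC network per group, takes the per-metabolite connectivity
#' difference `delta_i = C_i(a) - C_i(b)`, and builds a permutation null
#' by shuffling the group labels among the pooled samples (preserving the
#' group sizes) and recomputing both connectivity profiles per
#' permutation. Two-sided p-values are Benjamini-Hochberg adjusted across
#' metabolites; `q <= alpha` flags significance. Swapping the pair exactly
#' negates `delta` and leaves the p-values unchanged for the same seed.
#'
#' Two permutation nulls are available. `"pooled"` (default) compares
#' `|delta_obs_i|` against the permuted `|delta|` values of all
#' metabolites jointly, `p_i = (1 + #\{|delta_perm| >= |delta_obs_i|\}) /
#' (1 + m * n_perm)`; under the null the connectivity deltas of the
#' metabolites are exchangeable, and pooling gives p-value resolution far
#' below the `1 / (n_perm + 1)` floor, which BH needs when only a few of
#' many metabolites are truly rewired. `"per_metabolite"` uses each
#' metabolite's own permuted values only,
#' `p_i = (1 + #\{|delta_perm_i| >= |delta_obs_i|\}) / (1 + n_perm)`;
#' it makes no exchangeability assumption but at `n_perm` permutations
#' cannot produce p-values below `1 / (n_perm + 1)`.
#'
#' @inheritParams check_pair
#' @param n_perm Number of label permutations (default 1000).
#' @param n_iterations PCLRC iterations per network. The paper-scale
#'   setting is 1000; the default here (100) is the tractability knob for
#'   permutation use — each permutation refits two networks.
#' @param subsample_fraction,retention_quantile Passed to [pclrc_infer()].
#' @param alpha FDR threshold for the `significant` flag (default 0.05,
#'   inclusive).
#' @param statistic Connectivity statistic, see [connectivity()].
#' @param null Permutation null: `"pooled"` (default) or
#'   `"per_metabolite"`; see Details.
#' @param seed Master seed; per-permutation seeds are derived from it.
#' @return A tibble (class `metabnet_diffcon`) with one row per
#'   metabolite: `metabolite`, `connectivity_a`, `connectivity_b`,
#'   `delta`, `p_value`, `q_value`, `significant`.
#' @export
differential_connectivity <- function(data, pair, n_perm = 1000,
                                      n_iterations = 100,
                                      subsample_fraction = 0.75,
                                      retention_quantile = 0.30,
                                      alpha = 0.05,
                                      statistic = c("weighted_strength", "thresholded_degree"),
                                      null = c("pooled", "per_metabolite"),
                                      seed = 1L, label_col = "group") {
  statistic <- match.arg(statistic)
  null <- match.arg(null)
  data <- as_abundance(data, require_nonnegative = FALSE)
  check_pair(data, pair, label_col)
  if (n_perm < 99) warn("Fewer than 99 permutations; p-value floor above 0.01.")
  # Work in a canonical pair orientation so that swapping the pair only
  # flips the sign of delta (exact antisymmetry).
  canon <- sort(pair)
  flipped <- !identical(as.character(canon), as.character(pair))
  sub <- data[data[[label_col]] %in% pair, , drop = FALSE]
  labels <- sub[[label_col]]
  n_a <- sum(labels == canon[1])
  if (min(table(labels)) < 20) abort("Both groups need at least 20 samples.")
  x <- abundance_matrix(sub)
  if (anyNA(x)) abort("Missing values present; run impute_missing() first.")

  profile_pair <- function(assignment_a, perm_seed) {
    ca <- pclrc_profile(x[assignment_a, , drop = FALSE],
                        n_iterations, subsample_fraction, retention_quantile,
                        perm_seed, statistic)
    cb <- pclrc_profile(x[!assignment_a, , drop = FALSE],
                        n_iterations, subsample_fraction, retention_quantile,
                        perm_seed, statistic)
    list(ca = ca, cb = cb)
  }

  obs_assign <- labels == canon[1]
  obs <- profile_pair(obs_assign, derive_seed(seed, 0))
  delta_obs <- obs$ca - obs$cb

  perm_abs <- matrix(0, ncol(x), n_perm)
  for (b in seq_len(n_perm)) {
    perm_a <- with_seed(derive_seed(seed, b), {
      idx <- sample.int(nrow(x), n_a)
      seq_len(nrow(x)) %in% idx
    })
    perm <- profile_pair(perm_a, derive_seed(seed, n_perm + b))
    perm_abs[, b] <- abs(perm$ca - perm$cb)
  }
  p <- if (null == "per_metabolite") {
    (1 + rowSums(perm_abs >= abs(delta_obs))) / (1 + n_perm)
  } else {
    pooled <- sort(as.vector(perm_abs))
    m <- length(pooled)
    # count of pooled values >= |delta_obs_i| via binary search
    (1 + (m - findInterval(abs(delta_obs) - 1e-12, pooled))) / (1 + m)
  }
  q <- benjamini_hochberg(p)
  out <- tibble::tibble(
    metabolite = colnames(x),
    connectivity_a = if (flipped) obs$cb else obs$ca,
    connectivity_b = if (flipped) obs$ca else obs$cb,
    delta = if (flipped) -delta_obs else delta_obs,
    p_value = p,
    q_value = q,
    significant = q <= alpha
  )
  class(out) <- c("metabnet_diffcon", class(out))
  attr(out, "pair") <- pair
  attr(out, "settings") <- list(
    n_perm = n_perm, n_iterations = n_iterations,
    subsample_fraction = subsample_fraction,
    retention_quantile = retention_quantile, alpha = alpha,
    statistic = statistic, null = null, seed = as.integer(seed)
  )
  out
}

# Connectivity profile of one sample matrix through PCLRC.
pclrc_profile <- function(x, n_iterations, subsample_fraction,
                          retention_quantile, seed, statistic) {
  n <- nrow(x)
  ss <- floor(subsample_fraction * n)
  subsets <- with_seed(seed, {
    vapply(seq_len(n_iterations), function(i) sample.int(n, ss), integer(ss))
  })
  P <- cpp_pclrc_counts(x, matrix(as.integer(subsets), nrow = ss),
                        retention_quantile) / n_iterations
  R <- cpp_spearman(x)
  connectivity_vec(P, R, statistic)
}
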