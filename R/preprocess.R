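#' Flag multivariate outlier samples on a PCA confidence ellipse
#'
#' Samples are projected onto the first two principal components of the
#' unit-variance-scaled, pooled-group data. A sample is flagged when its
#' Mahalanobis distance from the score centroid exceeds the Hotelling
#' T-squared cutoff `2 (n - 1) / (n - 2) * qf(confidence, 2, n - 2)` — the
#' standard `confidence`-level ellipse for two components. Detection runs
#' once on all groups pooled; it is not iteratively re-fit after removal.
#'
#' @inheritParams as_abundance
#' @param confidence Ellipse confidence level (default 0.95).
#' @return An `outlier_report` object: a list with `removed_sample_ids`,
#'   `per_group_removed`, `scores` (tibble: sample_id, group, PC1, PC2,
#'   statistic, outlier), `center`, `shape`, `cutoff` and `confidence`.
#'   Use [remove_outliers()] to drop the flagged samples, `tidy()` for the
#'   per-sample table.
#' @export
detect_outliers <- function(data, confidence = 0.95) {
  data <- as_abundance(data, require_nonnegative = FALSE)
  x <- abundance_matrix(data)
  if (anyNA(x)) abort("Missing values present; run impute_missing() first.")
  n <- nrow(x)
  if (n < 5) abort("Need at least 5 samples for 2-component outlier detection.")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    drop <- colnames(x)[sds == 0]
    warn(paste0("Dropping constant metabolite(s) before scaling: ",
                paste(drop, collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE, rank. = 2)
  scores <- pc$x[, 1:2, drop = FALSE]
  ctr <- colMeans(scores)
  shape <- cov(scores)
  stat <- mahalanobis(scores, ctr, shape)
  cutoff <- if (confidence >= 1) Inf else 2 * (n - 1) / (n - 2) * qf(confidence, 2, n - 2)
  out <- stat > cutoff
  tab <- tibble::tibble(
    sample_id = data$sample_id, group = data$group,
    PC1 = scores[, 1], PC2 = scores[, 2],
    statistic = as.numeric(stat), outlier = out
  )
  structure(
    list(
      removed_sample_ids = data$sample_id[out],
      per_group_removed = table(factor(data$group)[out]),
      scores = tab, center = ctr, shape = shape,
      cutoff = cutoff, confidence = confidence
    ),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report> ", length(x$removed_sample_ids), "/",
      nrow(x$scores), " samples outside the ",
      format(100 * x$confidence), "% ellipse\n", sep = "")
  invisible(x)
}

#' @rdname detect_outliers
#' @param x An `outlier_report`.
#' @param ... Unused.
#' @method tidy outlier_report
#' @export
tidy.outlier_report <- function(x, ...) x$scores

#' Drop flagged outlier samples from an abundance table
#'
#' @inheritParams as_abundance
#' @param report An [detect_outliers()] report.
#' @return The table without the flagged samples.
#' @export
remove_outliers <- function(data, report) {
  stopifnot(inherits(report, "outlier_report"))
  data[!(data$sample_id %in% report$removed_sample_ids), , drop = FALSE]
}

#' Rank-based inverse normal (Blom) transform of a vector
#'
#' Maps each value to `qnorm((rank - offset) / (n - 2 * offset + 1))`, with
#' average ranks for ties. The default offset 3/8 is Blom's; the result is
#' a vector of (approximate) normal quantiles with the same ranks as the
#' input, so Spearman correlations are unchanged by the transform.
#'
#' @param x Numeric vector, length >= 2, not all equal.
#' @param offset Rank offset `k` (default `3/8`).
#' @return Numeric vector of z-scores.
#' @export
blom_transform <- function(x, offset = 3 / 8) {
  if (length(x) < 2) abort("Need at least 2 observations.")
  if (anyNA(x)) abort("Missing values not allowed; impute first.")
  if (diff(range(x)) == 0) abort("All values identical; ranks are undefined.")
  n <- length(x)
  r <- rank(x, ties.method = "average")
  qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Blom-normalise every metabolite of an abundance table
#'
#' Applies [blom_transform()] column-wise. The result contains z-scores
#' (negative values are expected).
#'
#' @inheritParams as_abundance
#' @inheritParams blom_transform
#' @return The transformed tibble.
#' @export
normalize_ranknorm <- function(data, offset = 3 / 8) {
  data <- as_abundance(data)
  for (m in metabolite_names(data)) data[[m]] <- blom_transform(data[[m]], offset)
  data
}

#' Square-root transform an abundance table
#'
#' Element-wise square root, the usual variance-stabilising step before
#' per-metabolite t-tests on MS intensities.
#'
#' @inheritParams as_abundance
#' @return The transformed tibble.
#' @export
sqrt_transform <- function(data) {
  data <- as_abundance(data)
  for (m in metabolite_names(data)) data[[m]] <- sqrt(data[[m]])
  data
}
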