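#' Resampled random-forest classification of two groups
#'
#' For each of `k` resampling rounds, `train_fraction` of the samples of
#' each group is drawn without replacement (stratified) as the training
#' set, a random forest is fitted with standard defaults (500 trees,
#' `mtry = floor(sqrt(p))`), and performance is scored on the held-out
#' remainder. The first element of `pair` is the case (positive) class:
#' sensitivity = TP / (TP + FN), specificity = TN / (TN + FP), accuracy =
#' (TP + TN) / total, and AUROC is the rank (Mann-Whitney) statistic on
#' the case-class probability scores. Reported values are the arithmetic
#' mean over the `k` rounds with percentile (2.5/97.5) intervals.
#'
#' @inheritParams check_pair
#' @param k Number of resampling rounds (default 100).
#' @param train_fraction Fraction of each group used for training
#'   (default 0.85).
#' @param ntree,mtry Forest size and candidate-split count
#'   (`NULL` = `floor(sqrt(p))`).
#' @param eval `"holdout"` scores the held-out fraction; `"oob"` scores
#'   the out-of-bag votes on the training samples instead.
#' @param seed Integer seed; the full result is reproducible.
#' @return A `metabnet_rf` object: `per_resample` metrics tibble,
#'   `summary` (metric, mean, ci_lo, ci_hi), `importance` (per-metabolite
#'   mean Gini importance) and `settings`. `tidy()` returns the summary,
#'   `glance()` a one-row overview.
#' @export
rf_classify <- function(data, pair, k = 100, train_fraction = 0.85,
                        ntree = 500, mtry = NULL,
                        eval = c("holdout", "oob"), seed = 1L,
                        label_col = "group") {
  eval <- match.arg(eval)
  data <- as_abundance(data, require_nonnegative = FALSE)
  check_pair(data, pair, label_col)
  if (k < 2) abort("`k` must be at least 2.")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie in (0, 1).")
  }
  sub <- data[data[[label_col]] %in% pair, , drop = FALSE]
  y <- factor(sub[[label_col]], levels = pair) # first level = case
  x <- abundance_matrix(sub)
  if (anyNA(x)) abort("Missing values present; run impute_missing() first.")
  if (min(table(y)) < 10) abort("Both groups need at least 10 samples.")
  mtry <- mtry %||% max(1, floor(sqrt(ncol(x))))

  rounds <- with_seed(seed, {
    lapply(seq_len(k), function(i) {
      rf_one_round(x, y, train_fraction, ntree, mtry, eval)
    })
  })
  per <- dplyr::bind_rows(lapply(rounds, `[[`, "metrics"))
  per$resample <- seq_len(k)
  imp <- rowMeans(vapply(rounds, `[[`, numeric(ncol(x)), "importance"))
  summary <- tidyr::pivot_longer(per, -"resample", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      ci_lo = unname(quantile(.data$value, 0.025)),
      ci_hi = unname(quantile(.data$value, 0.975)),
      .groups = "drop"
    )
  structure(
    list(
      pair = pair,
      per_resample = per[, c("resample", "accuracy", "sensitivity", "specificity", "auroc")],
      summary = summary,
      importance = tibble::tibble(metabolite = colnames(x), importance = imp),
      settings = list(k = k, train_fraction = train_fraction, ntree = ntree,
                      mtry = mtry, eval = eval, seed = as.integer(seed))
    ),
    class = "metabnet_rf"
  )
}

# One stratified resampling round; redraws (with a fresh draw from the
# current RNG stream) if an evaluation fold ends up with an empty class.
rf_one_round <- function(x, y, train_fraction, ntree, mtry, eval) {
  for (attempt in 1:20) {
    train <- unlist(lapply(levels(y), function(g) {
      idx <- which(y == g)
      sample(idx, floor(train_fraction * length(idx)))
    }))
    test <- setdiff(seq_along(y), train)
    if (length(test) == 0 || length(unique(y[test])) == 2) break
  }
  fit <- randomForest::randomForest(x[train, , drop = FALSE], y[train],
                                    ntree = ntree, mtry = mtry)
  if (eval == "holdout") {
    scores <- predict(fit, x[test, , drop = FALSE], type = "prob")[, 1]
    truth <- y[test]
  } else {
    scores <- fit$votes[, 1]
    truth <- y[train]
  }
  list(
    metrics = classification_metrics(truth, scores, levels(y)[1]),
    importance = fit$importance[, "MeanDecreaseGini"]
  )
}

#' Classification metrics from class-probability scores
#'
#' @param truth Factor or character of true labels.
#' @param scores Probability of the case class per sample.
#' @param case The positive class label.
#' @param threshold Score cutoff for calling a sample positive
#'   (default 0.5).
#' @return One-row tibble: accuracy, sensitivity, specificity, auroc.
#' @export
classification_metrics <- function(truth, scores, case, threshold = 0.5) {
  is_case <- truth == case
  called <- scores > threshold
  tp <- sum(called & is_case); fn <- sum(!called & is_case)
  tn <- sum(!called & !is_case); fp <- sum(called & !is_case)
  r <- rank(scores, ties.method = "average")
  n1 <- sum(is_case); n0 <- sum(!is_case)
  auroc <- if (n1 > 0 && n0 > 0) {
    (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else NA_real_
  tibble::tibble(
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (n1 > 0) tp / (tp + fn) else NA_real_,
    specificity = if (n0 > 0) tn / (tn + fp) else NA_real_,
    auroc = auroc
  )
}

#' @export
print.metabnet_rf <- function(x, ...) {
  cat("<metabnet_rf> ", paste(x$pair, collapse = " vs "), ", k = ",
      x$settings$k, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname rf_classify
#' @param x A `metabnet_rf` object.
#' @param ... Unused.
#' @method tidy metabnet_rf
#' @export
tidy.metabnet_rf <- function(x, ...) x$summary

#' @rdname rf_classify
#' @method glance metabnet_rf
#' @export
glance.metabnet_rf <- function(x, ...) {
  wide <- setNames(as.list(x$summary$mean), paste0("mean_", x$summary$metric))
  tibble::tibble(
    pair = paste(x$pair, collapse = " vs "), !!!wide,
    k = x$settings$k, ntree = x$settings$ntree
  )
}

#' Permutation significance of a random-forest model
#'
#' Group labels are permuted `n_perm` times; for each permutation the full
#' resampling harness is rerun (at a reduced `k`, for tractability — the
#' observed statistics are computed at the same reduced `k` so observed
#' and permuted values are exchangeable) and the mean of each metric is
#' recorded. The p-value of a metric is
#' `(1 + #\{permuted >= observed\}) / (1 + n_perm)`. Per-metabolite
#' importance p-values are computed the same way from the permuted-label
#' importances, with Benjamini-Hochberg adjustment across metabolites.
#'
#' @inheritParams rf_classify
#' @param n_perm Number of label permutations (default 1000).
#' @param k Resampling rounds per permutation (default 5; the paper-scale
#'   choice of 100 is available but slow).
#' @return List with `p_values` (tibble: metric, observed, p_value),
#'   `importance` (tibble: metabolite, importance, p_value, q_value) and
#'   `settings`.
#' @export
rf_permutation_test <- function(data, pair, n_perm = 1000, k = 5,
                                train_fraction = 0.85, ntree = 500,
                                mtry = NULL, seed = 1L, label_col = "group") {
  if (n_perm < 99) warn("Fewer than 99 permutations; p-value floor above 0.01.")
  data <- as_abundance(data, require_nonnegative = FALSE)
  check_pair(data, pair, label_col)
  obs <- rf_classify(data, pair, k = k, train_fraction = train_fraction,
                     ntree = ntree, mtry = mtry, seed = derive_seed(seed, 0),
                     label_col = label_col)
  metric_names <- obs$summary$metric
  obs_means <- setNames(obs$summary$mean, metric_names)
  sub <- data[data[[label_col]] %in% pair, , drop = FALSE]
  perms <- lapply(seq_len(n_perm), function(b) {
    shuffled <- sub
    shuffled[[label_col]] <- with_seed(derive_seed(seed, b),
                                       sample(sub[[label_col]]))
    fit <- rf_classify(shuffled, pair, k = k, train_fraction = train_fraction,
                       ntree = ntree, mtry = mtry,
                       seed = derive_seed(seed, n_perm + b),
                       label_col = label_col)
    list(means = setNames(fit$summary$mean, fit$summary$metric),
         importance = fit$importance$importance)
  })
  perm_means <- do.call(rbind, lapply(perms, `[[`, "means"))
  p_values <- vapply(metric_names, function(m) {
    (1 + sum(perm_means[, m] >= obs_means[[m]])) / (1 + n_perm)
  }, 0)
  perm_imp <- do.call(rbind, lapply(perms, `[[`, "importance"))
  imp_p <- vapply(seq_len(ncol(perm_imp)), function(j) {
    (1 + sum(perm_imp[, j] >= obs$importance$importance[j])) / (1 + n_perm)
  }, 0)
  importance <- obs$importance
  importance$p_value <- imp_p
  importance$q_value <- benjamini_hochberg(imp_p)
  list(
    p_values = tibble::tibble(
      metric = metric_names, observed = unname(obs_means),
      p_value = unname(p_values)
    ),
    importance = importance,
    settings = list(n_perm = n_perm, k = k, ntree = ntree,
                    train_fraction = train_fraction, seed = as.integer(seed))
  )
}
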