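#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone, clipped at 1),
#' delegated to `stats::p.adjust(method = "BH")` after validating the
#' inputs. Shared by the univariate, differential-connectivity and
#' enrichment stages so all of them use the identical correction.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (anyNA(p_values) || any(!is.finite(p_values))) abort("p-values must be finite.")
  if (any(p_values < 0 | p_values > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p_values, method = "BH")
}

#' Per-metabolite two-group Student's t-tests with FDR control
#'
#' For every metabolite, a two-sided pooled-variance ("Student's") t-test
#' compares the two groups; Benjamini-Hochberg adjustment is applied across
#' all metabolites of the comparison, and `q < 0.05` flags significance.
#' Apply [sqrt_transform()] first to variance-stabilise raw intensities.
#'
#' @inheritParams check_pair
#' @param welch Use the Welch (unequal-variance) statistic instead of the
#'   pooled-variance one.
#' @param alpha FDR threshold for the `significant` flag (default 0.05).
#' @return A tibble with one row per metabolite: `metabolite`, `pair`,
#'   `mean_a`, `mean_b`, `t_statistic`, `p_value`, `q_value`,
#'   `significant`.
#' @export
t_test_all <- function(data, pair, welch = FALSE, alpha = 0.05,
                       label_col = "group") {
  data <- as_abundance(data, require_nonnegative = FALSE)
  check_pair(data, pair, label_col)
  xa <- group_matrix(data, pair[1], label_col)
  xb <- group_matrix(data, pair[2], label_col)
  if (nrow(xa) < 3 || nrow(xb) < 3) abort("Both groups need at least 3 samples.")
  res <- purrr::map(metabolite_names(data), function(m) {
    a <- xa[, m]; b <- xb[, m]
    st <- t_stat(a, b, welch)
    tibble::tibble(
      metabolite = m,
      pair = paste(pair, collapse = " vs "),
      mean_a = mean(a), mean_b = mean(b),
      t_statistic = st$t, p_value = st$p
    )
  })
  out <- dplyr::bind_rows(res)
  out$q_value <- benjamini_hochberg(out$p_value)
  out$significant <- out$q_value < alpha
  out
}

t_stat <- function(a, b, welch = FALSE) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  if (welch) {
    se2 <- va / na + vb / nb
    if (se2 == 0) {
      warn("Zero variance in both groups; p set to 1.")
      return(list(t = 0, p = 1))
    }
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 == 0) {
      warn("Zero pooled variance; p set to 1.")
      return(list(t = 0, p = 1))
    }
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  list(t = t, p = 2 * pt(-abs(t), df))
}
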