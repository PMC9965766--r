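#' Canonical compound names
#'
#' Lowercases, strips punctuation and collapses whitespace so that
#' trivially different spellings ("Hippuric acid", "hippuric-acid") match.
#' No fuzzy matching is attempted; supply a synonyms table for anything
#' beyond this.
#'
#' @param x Character vector of compound names.
#' @return Canonicalised character vector.
#' @export
canonical_compound <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- stringr::str_replace_all(x, "[[:punct:]]+", " ")
  stringr::str_replace_all(x, "\\s+", " ") |> trimws()
}

#' Read a pathway library from TSV
#'
#' Expected columns: `pathway_id`, `pathway_name`, `compound`, and
#' optionally `importance` (non-negative; defaults to 1 per compound, in
#' which case the impact score reduces to the matched fraction `k / K`).
#' The union of all compounds is the reference universe for the
#' hypergeometric test.
#'
#' @param path TSV path.
#' @return A `pathway_library`: list with `pathways` (tibble: pathway_id,
#'   pathway_name, compounds list-column, importance list-column) and
#'   `universe` (character vector of canonical compound names).
#' @export
read_pathway_library <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("pathway_id", "pathway_name", "compound")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    abort(paste0("Library lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"importance" %in% names(tab)) tab$importance <- 1
  if (any(tab$importance < 0)) abort("Importance values must be non-negative.")
  tab$compound <- canonical_compound(tab$compound)
  pathways <- tab |>
    dplyr::group_by(.data$pathway_id, .data$pathway_name) |>
    dplyr::summarise(
      compounds = list(.data$compound),
      importance = list(setNames(.data$importance, .data$compound)),
      .groups = "drop"
    )
  if (any(vapply(pathways$importance, sum, 0) <= 0)) {
    abort("Each pathway needs positive total importance.")
  }
  structure(
    list(pathways = pathways, universe = sort(unique(tab$compound))),
    class = "pathway_library"
  )
}

#' @export
print.pathway_library <- function(x, ...) {
  cat("<pathway_library> ", nrow(x$pathways), " pathways, ",
      length(x$universe), " compounds\n", sep = "")
  invisible(x)
}

#' Pathway impact score
#'
#' The sum of the importance measures of the matched compounds divided by
#' the sum of the importance measures of all compounds of the pathway; a
#' number in \[0, 1\].
#'
#' @param matched Character vector of matched (canonical) compound names,
#'   a subset of the pathway's members.
#' @param importance Named numeric vector of per-compound importances for
#'   one pathway.
#' @return The impact score.
#' @export
impact_score <- function(matched, importance) {
  bad <- setdiff(matched, names(importance))
  if (length(bad) > 0) {
    abort(paste0("Matched compounds not in pathway: ", paste(bad, collapse = ", ")))
  }
  sum(importance[matched]) / sum(importance)
}

#' Hypergeometric pathway over-representation
#'
#' For each pathway with `K` members in a universe of `N` library
#' compounds, and a query of `n` universe-matched metabolites of which `k`
#' fall in the pathway, the enrichment p-value is the upper tail
#' `P(X >= k)` with `X ~ Hypergeometric(N, K, n)`. P-values are
#' Benjamini-Hochberg adjusted across all pathways, and the result is
#' filtered to pathways whose impact score exceeds `impact_min`.
#'
#' @param query Character vector of metabolite names (canonicalised
#'   internally).
#' @param lib A [read_pathway_library()] object.
#' @param synonyms Optional two-column data frame (`from`, `to`) of name
#'   synonyms applied after canonicalization.
#' @param impact_min Impact filter (default 0.01, exclusive). Set to
#'   `-Inf` to keep everything.
#' @param alpha FDR threshold for the `significant` flag (default 0.05).
#' @return Tibble (class `metabnet_enrichment`): `pathway_id`,
#'   `pathway_name`, `n_members`, `k_matched`, `p_value`, `q_value`,
#'   `impact`, `significant`, `matched` (list-column).
#' @export
hypergeometric_enrich <- function(query, lib, synonyms = NULL,
                                  impact_min = 0.01, alpha = 0.05) {
  stopifnot(inherits(lib, "pathway_library"))
  q <- unique(canonical_compound(query))
  if (!is.null(synonyms)) {
    syn_from <- canonical_compound(synonyms$from)
    syn_to <- canonical_compound(synonyms$to)
    hit <- match(q, syn_from)
    q[!is.na(hit)] <- syn_to[hit[!is.na(hit)]]
    q <- unique(q)
  }
  matched_universe <- intersect(q, lib$universe)
  N <- length(lib$universe)
  n <- length(matched_universe)
  if (n == 0) {
    warn("No query metabolite matches the library universe.")
  }
  res <- purrr::pmap(lib$pathways, function(pathway_id, pathway_name, compounds, importance) {
    members <- unique(compounds)
    K <- length(members)
    matched <- intersect(matched_universe, members)
    k <- length(matched)
    p <- if (n == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(
      pathway_id = pathway_id, pathway_name = pathway_name,
      n_members = K, k_matched = k, p_value = p,
      impact = impact_score(matched, importance),
      matched = list(matched)
    )
  })
  out <- dplyr::bind_rows(res)
  out$q_value <- benjamini_hochberg(out$p_value)
  out$significant <- out$q_value <= alpha
  out <- out[out$impact > impact_min, , drop = FALSE]
  out <- dplyr::arrange(out, .data$p_value, .data$pathway_id)
  out <- out[, c("pathway_id", "pathway_name", "n_members", "k_matched",
                 "p_value", "q_value", "impact", "significant", "matched")]
  class(out) <- c("metabnet_enrichment", class(out))
  out
}
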