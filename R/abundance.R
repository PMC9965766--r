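#' Abundance tables
#'
#' The universal pipeline input is a tibble in "wide" layout: one row per
#' sample, a `sample_id` column, a `group` column (e.g. CRC / PP / CTR), an
#' optional `subgroup` column (e.g. colon / rectal within CRC), and one
#' numeric column per metabolite holding non-negative MS signal intensities
#' (counts per second). `as_abundance()` validates a data frame against this
#' contract and canonicalises metabolite names.
#'
#' Missing intensities are kept as `NA` (never silently zeroed); use
#' [impute_missing()] before analysis stages that require complete data.
#'
#' @param data A data frame with `sample_id`, `group`, optionally `subgroup`,
#'   and numeric metabolite columns.
#' @param require_nonnegative Require all intensities to be `>= 0`. Set to
#'   `FALSE` for tables that have already been variance-stabilised or
#'   normalised to z-scores.
#' @return A validated tibble (invisibly the same data, as a tibble).
#' @examples
#' tbl <- tibble::tibble(
#'   sample_id = c("s1", "s2"), group = c("CRC", "CTR"),
#'   m1 = c(1, 2), m2 = c(3, 4)
#' )
#' as_abundance(tbl)
#' @export
as_abundance <- function(data, require_nonnegative = TRUE) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  data <- tibble::as_tibble(data)
  if (!"sample_id" %in% names(data)) abort("`data` must have a `sample_id` column.")
  if (!"group" %in% names(data)) abort("`data` must have a `group` column.")
  data$sample_id <- as.character(data$sample_id)
  data$group <- as.character(data$group)

  dup <- data$sample_id[duplicated(data$sample_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate sample ids: ", paste(unique(dup), collapse = ", ")))
  }
  if (anyNA(data$group)) abort("Every sample must carry a group label.")

  mets <- metabolite_names(data)
  if (length(mets) == 0) abort("No metabolite columns found.")
  canon <- tolower(trimws(mets))
  if (anyDuplicated(canon)) {
    abort(paste0(
      "Duplicate metabolite names after canonicalization: ",
      paste(unique(mets[duplicated(canon) | duplicated(canon, fromLast = TRUE)]),
            collapse = ", ")
    ))
  }
  trimmed <- trimws(mets)
  names(data)[match(mets, names(data))] <- trimmed

  for (m in trimmed) {
    if (!is.numeric(data[[m]])) {
      abort(paste0("Metabolite column `", m, "` is not numeric."))
    }
    if (require_nonnegative && any(data[[m]] < 0, na.rm = TRUE)) {
      bad <- which(data[[m]] < 0)[1]
      abort(paste0(
        "Negative intensity in metabolite `", m, "`, sample `",
        data$sample_id[bad], "`."
      ))
    }
  }
  data
}

#' Metabolite column names of an abundance table
#'
#' Every column other than `sample_id`, `group` and `subgroup` is treated as
#' a metabolite.
#'
#' @inheritParams as_abundance
#' @return Character vector of metabolite names.
#' @export
metabolite_names <- function(data) {
  setdiff(names(data), c("sample_id", "group", "subgroup"))
}

#' Extract the samples-by-metabolites matrix
#'
#' @inheritParams as_abundance
#' @return Numeric matrix with sample ids as row names.
#' @export
abundance_matrix <- function(data) {
  mets <- metabolite_names(data)
  m <- as.matrix(data[, mets, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- data$sample_id
  m
}

#' Per-group sample counts
#'
#' @inheritParams as_abundance
#' @return A tibble with columns `group` and `n`.
#' @export
group_sizes <- function(data) {
  dplyr::count(data, .data$group, name = "n")
}

#' Default group-label aliases
#'
#' Public exports of cohort tables label groups inconsistently
#' ("control", "healthy", "Normal" all mean CTR). The reader canonicalises
#' labels through this alias map; extend or replace it for other cohorts.
#'
#' @return Named list mapping canonical label to a character vector of
#'   case-insensitive aliases.
#' @export
default_group_aliases <- function() {
  list(
    CRC = c("crc", "colorectal cancer", "cancer"),
    PP  = c("pp", "polyp", "polyps", "polyposis"),
    CTR = c("ctr", "control", "controls", "healthy", "normal")
  )
}

#' Canonicalise group labels through an alias map
#'
#' @param x Character vector of raw labels.
#' @param aliases Alias map as produced by [default_group_aliases()]; `NULL`
#'   disables canonicalisation (labels pass through unchanged).
#' @return Character vector of canonical labels.
#' @export
canonicalize_groups <- function(x, aliases = default_group_aliases()) {
  if (is.null(aliases)) return(as.character(x))
  lut <- unlist(lapply(names(aliases), function(g) {
    setNames(rep(g, length(aliases[[g]]) + 1), tolower(c(g, aliases[[g]])))
  }))
  key <- tolower(trimws(as.character(x)))
  out <- unname(lut[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    abort(paste0(
      "Unknown group label(s): ", paste(bad, collapse = ", "),
      ". Allowed: ", paste(names(aliases), collapse = ", "),
      " (aliases: ", paste(unlist(aliases), collapse = ", "), ")."
    ))
  }
  out
}

#' Impute missing intensities by the half-minimum rule
#'
#' Standard MS practice for values below the detection limit: a missing
#' entry is replaced by half the minimum positive observed value of that
#' metabolite. A metabolite missing in more than `max_missing` of the
#' samples of any one group is rejected with an error, because imputation
#' would then dominate its group distribution.
#'
#' @inheritParams as_abundance
#' @param max_missing Maximum tolerated fraction of missing values per
#'   metabolite within each group (default 0.2).
#' @return The table with no remaining `NA` intensities.
#' @export
impute_missing <- function(data, max_missing = 0.2) {
  data <- as_abundance(data)
  mets <- metabolite_names(data)
  for (m in mets) {
    frac <- tapply(is.na(data[[m]]), data$group, mean)
    if (any(frac > max_missing)) {
      g <- names(frac)[which.max(frac)]
      abort(paste0(
        "Metabolite `", m, "` is missing in ", round(100 * max(frac)), "% of ",
        "group ", g, " samples (limit ", round(100 * max_missing), "%)."
      ))
    }
    if (anyNA(data[[m]])) {
      pos <- data[[m]][!is.na(data[[m]]) & data[[m]] > 0]
      if (length(pos) == 0) {
        abort(paste0("Metabolite `", m, "` has no positive values to impute from."))
      }
      data[[m]][is.na(data[[m]])] <- min(pos) / 2
    }
  }
  data
}

#' Validate a two-group comparison
#'
#' @inheritParams as_abundance
#' @param pair Character vector of two distinct group labels, e.g.
#'   `c("CRC", "CTR")`. The first label is the "case" (positive) group.
#' @param label_col Column holding the labels (`"group"` or `"subgroup"`).
#' @return `pair`, validated.
#' @export
check_pair <- function(data, pair, label_col = "group") {
  if (length(pair) != 2 || anyNA(pair) || pair[1] == pair[2]) {
    abort("`pair` must be two distinct group labels.")
  }
  present <- unique(data[[label_col]])
  missing <- setdiff(pair, present)
  if (length(missing) > 0) {
    abort(paste0(
      "Group(s) not present in `", label_col, "`: ",
      paste(missing, collapse = ", ")
    ))
  }
  pair
}

# Rows of `data` belonging to one label; matrix of their intensities.
group_matrix <- function(data, group, label_col = "group") {
  abundance_matrix(data[data[[label_col]] == group, , drop = FALSE])
}
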