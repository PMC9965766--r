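#' Read an abundance table
#'
#' Two layouts are supported. `wide_csv` is the canonical interchange
#' format: first column `sample_id`, second `group`, optional third
#' `subgroup`, remaining columns metabolite intensities. `mwtab_flat` is a
#' best-effort reader for the flat `MS_METABOLITE_DATA` tabular block of a
#' Metabolomics Workbench export (metabolites in rows, samples in columns,
#' with `Samples` and `Factors` header lines); it is not a general mwTab
#' parser.
#'
#' @param path Path to the file.
#' @param format `"wide_csv"` or `"mwtab_flat"`.
#' @param aliases Group-label alias map (see [default_group_aliases()]);
#'   `NULL` keeps labels verbatim.
#' @return A validated abundance tibble (see [as_abundance()]). Missing
#'   values are kept as `NA`.
#' @export
read_abundance <- function(path, format = c("wide_csv", "mwtab_flat"),
                           aliases = default_group_aliases()) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- switch(format,
    wide_csv = read_wide_csv(path),
    mwtab_flat = read_mwtab_flat(path)
  )
  raw$group <- canonicalize_groups(raw$group, aliases)
  as_abundance(raw)
}

read_wide_csv <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  if (length(hdr) >= 3) {
    met_hdr <- tolower(trimws(hdr[-(1:2)]))
    dupm <- met_hdr[duplicated(met_hdr) & met_hdr != "subgroup"]
    if (length(dupm) > 0) {
      abort(paste0("Duplicate metabolite columns: ", paste(unique(dupm), collapse = ", ")))
    }
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, locale = readr::locale(decimal_mark = "."))
  if (ncol(df) < 3) abort("wide_csv needs sample_id, group and at least one metabolite column.")
  names(df)[1] <- "sample_id"
  names(df)[2] <- "group"
  if (ncol(df) >= 3 && tolower(names(df)[3]) == "subgroup") names(df)[3] <- "subgroup"
  mets <- metabolite_names(df)
  for (m in mets) {
    cell <- df[[m]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & cell != "" & is.na(num))
    if (length(bad) > 0) {
      abort(paste0(
        "Non-numeric value `", cell[bad[1]], "` in column `", m,
        "`, row ", bad[1], " (sample `", df$sample_id[bad[1]], "`)."
      ))
    }
    num[!is.na(cell) & cell == ""] <- NA_real_
    df[[m]] <- num
  }
  df
}

read_mwtab_flat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^MS_METABOLITE_DATA_START", lines)
  end <- grep("^MS_METABOLITE_DATA_END", lines)
  if (length(start) != 1 || length(end) != 1 || end <= start) {
    abort("No MS_METABOLITE_DATA block found.")
  }
  block <- lines[(start + 1):(end - 1)]
  fields <- strsplit(block, "\t", fixed = TRUE)
  tag <- vapply(fields, `[`, "", 1)
  samp_i <- which(tolower(tag) == "samples")
  fact_i <- which(tolower(tag) == "factors")
  if (length(samp_i) != 1) abort("mwtab_flat block lacks a Samples line.")
  if (length(fact_i) != 1) abort("mwtab_flat block lacks a Factors line.")
  sample_ids <- fields[[samp_i]][-1]
  factors <- fields[[fact_i]][-1]
  # Factor cells look like "Diagnosis:CRC" (possibly several ';'-separated
  # factors); the last ':'-field of the first factor is the group label.
  groups <- vapply(strsplit(factors, ";", fixed = TRUE), function(f) {
    parts <- strsplit(trimws(f[1]), ":", fixed = TRUE)[[1]]
    trimws(parts[length(parts)])
  }, "")
  met_rows <- setdiff(seq_along(block), c(samp_i, fact_i))
  met_names <- tag[met_rows]
  values <- lapply(fields[met_rows], function(f) {
    cell <- f[-1]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & cell != "" & is.na(num))
    if (length(bad) > 0) {
      abort(paste0("Non-numeric value `", cell[bad[1]], "` for metabolite `", f[1], "`."))
    }
    length(num) <- length(sample_ids)
    num
  })
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup) > 0) abort(paste0("Duplicate sample ids: ", paste(unique(dup), collapse = ", ")))
  df <- tibble::tibble(sample_id = sample_ids, group = groups)
  for (i in seq_along(met_names)) df[[met_names[i]]] <- values[[i]]
  df
}

#' Write an abundance table as wide CSV
#'
#' @inheritParams as_abundance
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(data, path) {
  data <- as_abundance(data, require_nonnegative = FALSE)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Write an association network to disk
#'
#' `graphml` preserves the full graph (node `connectivity` attribute, edge
#' `weight` and `probability`) through igraph. `edge_tsv` writes a flat
#' table with columns `source`, `target`, `weight`, `probability`; isolated
#' nodes are recorded as rows with an empty `target` so the node set
#' round-trips.
#'
#' @param net An [build_network()] result.
#' @param path Output path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "assoc_network"))
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    edges <- net$edges
    isolated <- setdiff(net$nodes$name, unique(c(edges$from, edges$to)))
    tab <- tibble::tibble(
      source = c(edges$from, isolated),
      target = c(edges$to, rep(NA_character_, length(isolated))),
      weight = c(edges$weight, rep(NA_real_, length(isolated))),
      probability = c(edges$probability, rep(NA_real_, length(isolated)))
    )
    tab <- dplyr::arrange(tab, .data$source, .data$target)
    readr::write_tsv(tab, path, progress = FALSE)
  }
  invisible(path)
}

#' Read an association network written by [write_network()]
#'
#' @param path Input path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @param p_min,r_min Threshold metadata to attach (edge_tsv does not store
#'   them).
#' @return An `assoc_network` object.
#' @export
read_network <- function(path, format = c("graphml", "edge_tsv"),
                         p_min = NA_real_, r_min = NA_real_) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble::tibble(
      name = igraph::V(g)$name,
      connectivity = igraph::V(g)$connectivity %||% rep(NA_real_, igraph::vcount(g))
    )
    el <- igraph::as_edgelist(g)
    edges <- tibble::tibble(
      from = el[, 1], to = el[, 2],
      weight = igraph::E(g)$weight %||% rep(NA_real_, nrow(el)),
      probability = igraph::E(g)$probability %||% rep(NA_real_, nrow(el))
    )
  } else {
    tab <- readr::read_tsv(path, col_types = "ccdd", progress = FALSE)
    iso <- is.na(tab$target) | tab$target == ""
    edges <- tibble::tibble(
      from = tab$source[!iso], to = tab$target[!iso],
      weight = tab$weight[!iso], probability = tab$probability[!iso]
    )
    nodes <- tibble::tibble(name = unique(c(tab$source, edges$to)))
    nodes$connectivity <- node_connectivity_from_edges(nodes$name, edges)
  }
  new_assoc_network(nodes, edges, p_min, r_min)
}

#' Write a results table as TSV
#'
#' Rows are ordered deterministically (by `metabolite`, then `pair` /
#' `comparison` when present, then remaining columns as-is) and numeric
#' values keep full precision.
#'
#' @param rows A data frame of per-metabolite results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  rows <- tibble::as_tibble(rows)
  keys <- intersect(c("metabolite", "pair", "comparison", "pathway_id"), names(rows))
  if (length(keys) > 0) {
    rows <- dplyr::arrange(rows, dplyr::across(dplyr::all_of(keys)))
  }
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}
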