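#' Pipeline configuration
#'
#' Collects every tunable of the full analysis flow, defaulting to the
#' study-scale settings: 95% outlier ellipse, Blom offset 3/8,
#' square-root input for the t-tests, 100 random-forest resamplings
#' retaining 85% per group with 1000 label permutations, PCLRC at 1000
#' iterations / 0.75 subsample fraction / 0.30 retention, edge thresholds
#' `p >= 0.95` and `|r| >= 0.6`, FDR 0.05, impact filter 0.01. Any element
#' can be overridden through `...` (nested lists are merged), or loaded
#' from a YAML file whose keys mirror the defaults.
#'
#' @param input Path to an abundance table, or `NULL` to simulate from
#'   `design`.
#' @param design A [synthetic_design()] used when `input` is `NULL`
#'   (default: [serum_cohort_design()]).
#' @param out_dir Output directory.
#' @param seed Master seed for every stochastic stage.
#' @param ... Overrides of the defaults listed above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, design = NULL,
                            out_dir = tempfile("metabnet_run_"),
                            seed = 1L, ...) {
  defaults <- list(
    input = input, format = "wide_csv", design = design,
    out_dir = out_dir, seed = as.integer(seed),
    outlier_confidence = 0.95,
    blom_offset = 3 / 8,
    univariate_input = "sqrt_raw",
    pairs = NULL, # NULL = all pairs of observed groups
    rf = list(k = 100, train_fraction = 0.85, ntree = 500,
              n_perm = 1000, k_perm = 5, eval = "holdout"),
    pclrc = list(n_iterations = 1000, subsample_fraction = 0.75,
                 retention_quantile = 0.30),
    diffcon = list(n_perm = 1000, n_iterations = 100,
                   statistic = "weighted_strength"),
    thresholds = list(p_min = 0.95, r_min = 0.6, fdr = 0.05, impact = 0.01),
    library = NULL, # pathway library TSV; NULL skips enrichment
    reference_group = NULL # enrichment compares others against this group
  )
  cfg <- merge_config(defaults, list(...))
  bad <- with(cfg$thresholds, p_min < 0 || p_min > 1 || r_min < 0 || r_min > 1 ||
                fdr <= 0 || fdr >= 1)
  if (bad) abort("Thresholds out of range.")
  if (!cfg$univariate_input %in% c("sqrt_raw", "int", "sqrt_int")) {
    abort("`univariate_input` must be one of sqrt_raw, int, sqrt_int.")
  }
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data ingestion (or simulation), PCA-ellipse outlier
#' removal, Blom normalisation, per-metabolite t-tests, resampled
#' random-forest classification, per-group PCLRC network inference with
#' |r|-thresholded network export, differential connectivity per pair,
#' topology metrics with PCA comparison, and (when a pathway library is
#' configured) hypergeometric enrichment of the differentially connected
#' metabolites. Every output lands under `config$out_dir`; a JSON
#' manifest records file paths, stage parameters, seeds and wall-clock
#' seconds. The same configuration and seed reproduce every output
#' exactly.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$input) && !file.exists(config$input)) {
    abort(paste0("Input file not found: ", config$input))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  out <- function(...) file.path(config$out_dir, paste0(...))
  stage <- function(name, params, code) {
    t0 <- proc.time()[["elapsed"]]
    files <- code
    manifest$stages[[name]] <<- list(
      params = params, files = as.list(files),
      seconds = round(proc.time()[["elapsed"]] - t0, 3)
    )
    files
  }

  # -- ingest / simulate ------------------------------------------------
  st <- new.env(parent = emptyenv())
  stage("ingest", list(input = config$input %||% "simulated"), {
    if (is.null(config$input)) {
      design <- config$design %||% serum_cohort_design(derive_seed(config$seed, 1))
      st$raw <- simulate_abundance(design)
    } else {
      st$raw <- read_abundance(config$input, config$format)
    }
    st$raw <- impute_missing(st$raw)
    write_abundance(st$raw, out("raw.csv"))
  })

  # -- qc ---------------------------------------------------------------
  stage("qc", list(confidence = config$outlier_confidence), {
    rep <- detect_outliers(st$raw, config$outlier_confidence)
    st$clean <- remove_outliers(st$raw, rep)
    write_results_table(tidy(rep), out("outliers.tsv"))
    write_abundance(st$clean, out("clean.csv"))
    c(out("outliers.tsv"), out("clean.csv"))
  })
  clean <- st$clean
  groups <- sort(unique(clean$group))
  pairs <- config$pairs %||% utils::combn(groups, 2, simplify = FALSE)
  pairs <- lapply(pairs, as.character)

  # -- normalisation ----------------------------------------------------
  stage("normalize", list(offset = config$blom_offset), {
    st$normalized <- normalize_ranknorm(clean, config$blom_offset)
    write_abundance(st$normalized, out("normalized.csv"))
  })
  normalized <- st$normalized
  univariate_data <- switch(config$univariate_input,
    sqrt_raw = sqrt_transform(clean),
    int = normalized,
    sqrt_int = normalize_ranknorm(sqrt_transform(clean), config$blom_offset)
  )

  # -- univariate -------------------------------------------------------
  stage("univariate", list(input = config$univariate_input,
                           fdr = config$thresholds$fdr), {
    tab <- dplyr::bind_rows(lapply(pairs, function(p) {
      t_test_all(univariate_data, p, alpha = config$thresholds$fdr)
    }))
    write_results_table(tab, out("univariate.tsv"))
  })

  # -- classification ---------------------------------------------------
  stage("classify", config$rf, {
    files <- character(0)
    for (p in pairs) {
      fit <- rf_classify(normalized, p, k = config$rf$k,
                         train_fraction = config$rf$train_fraction,
                         ntree = config$rf$ntree, eval = config$rf$eval,
                         seed = derive_seed(config$seed, 10 + which_pair(pairs, p)))
      res <- fit$summary
      if (config$rf$n_perm > 0) {
        pt <- rf_permutation_test(
          normalized, p, n_perm = config$rf$n_perm, k = config$rf$k_perm,
          train_fraction = config$rf$train_fraction, ntree = config$rf$ntree,
          seed = derive_seed(config$seed, 20 + which_pair(pairs, p))
        )
        res <- dplyr::left_join(res, pt$p_values[, c("metric", "p_value")],
                                by = "metric")
        write_results_table(pt$importance,
                            out("rf_importance_", pair_tag(p), ".tsv"))
        files <- c(files, out("rf_importance_", pair_tag(p), ".tsv"))
      }
      res$pair <- paste(p, collapse = " vs ")
      f <- out("rf_", pair_tag(p), ".tsv")
      write_results_table(res, f)
      files <- c(files, f)
    }
    files
  })

  # -- networks ---------------------------------------------------------
  st$pclrc_fits <- list()
  stage("network", c(config$pclrc, config$thresholds[c("p_min", "r_min")]), {
    files <- character(0)
    for (g in groups) {
      fit <- pclrc_infer(
        clean[clean$group == g, ], n_iterations = config$pclrc$n_iterations,
        subsample_fraction = config$pclrc$subsample_fraction,
        retention_quantile = config$pclrc$retention_quantile,
        seed = derive_seed(config$seed, 30 + match(g, groups))
      )
      st$pclrc_fits[[g]] <- fit
      net <- build_network(fit, config$thresholds$p_min, config$thresholds$r_min)
      f <- out("network_", g, ".graphml")
      write_network(net, f, "graphml")
      files <- c(files, f)
    }
    files
  })

  # -- differential connectivity ---------------------------------------
  st$diffcon_results <- list()
  stage("diffcon", config$diffcon, {
    files <- character(0)
    for (p in pairs) {
      dc <- differential_connectivity(
        clean, p, n_perm = config$diffcon$n_perm,
        n_iterations = config$diffcon$n_iterations,
        subsample_fraction = config$pclrc$subsample_fraction,
        retention_quantile = config$pclrc$retention_quantile,
        alpha = config$thresholds$fdr, statistic = config$diffcon$statistic,
        seed = derive_seed(config$seed, 40 + which_pair(pairs, p))
      )
      st$diffcon_results[[pair_tag(p)]] <- dc
      f <- out("diffcon_", pair_tag(p), ".tsv")
      write_results_table(tibble::as_tibble(dc), f)
      files <- c(files, f)
    }
    files
  })

  # -- topology ---------------------------------------------------------
  stage("topology", list(), {
    tables <- lapply(st$pclrc_fits, function(fit) {
      node_topology(build_network(fit, config$thresholds$p_min,
                                  config$thresholds$r_min))
    })
    stacked <- dplyr::bind_rows(
      lapply(names(tables), function(g) dplyr::mutate(tables[[g]], network = g))
    )
    readr::write_tsv(stacked, out("topology.tsv"), progress = FALSE)
    pca <- topology_pca(tables)
    readr::write_tsv(pca$scores, out("topology_pca_scores.tsv"), progress = FALSE)
    readr::write_tsv(pca$centroid_distances, out("topology_pca_centroids.tsv"),
                     progress = FALSE)
    c(out("topology.tsv"), out("topology_pca_scores.tsv"),
      out("topology_pca_centroids.tsv"))
  })

  # -- enrichment -------------------------------------------------------
  if (!is.null(config$library)) {
    stage("enrich", list(library = config$library,
                         impact = config$thresholds$impact), {
      lib <- read_pathway_library(config$library)
      files <- character(0)
      for (tag in names(st$diffcon_results)) {
        dc <- st$diffcon_results[[tag]]
        hits <- dc$metabolite[dc$significant]
        if (length(hits) == 0) next
        enr <- hypergeometric_enrich(hits, lib,
                                     impact_min = config$thresholds$impact,
                                     alpha = config$thresholds$fdr)
        f <- out("enrichment_", tag, ".tsv")
        write_results_table(dplyr::select(tibble::as_tibble(enr), -"matched"), f)
        files <- c(files, f)
      }
      files
    })
  }

  manifest_path <- out("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Recursive override merge so partial nested overrides (e.g. rf = list(k = 5))
# keep the remaining defaults.
merge_config <- function(defaults, overrides) {
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(overrides[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], overrides[[nm]])
    } else {
      defaults[nm] <- overrides[nm]
    }
  }
  defaults
}

pair_tag <- function(p) paste(p, collapse = "_")
which_pair <- function(pairs, p) which(vapply(pairs, identical, TRUE, p))
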