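toy_library <- function() {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  lines <- c(
    "pathway_id\tpathway_name\tcompound\timportance",
    paste0("P1\tglycolysis\t", c("glucose", "lactate", "pyruvate", "pep", "f16bp"),
           "\t", c(0.5, 0.3, 0.2, 0.4, 0.1)),
    paste0("P2\ttca\t", c("citrate", "malate", "succinate", "fumarate"),
           "\t", c(1, 1, 1, 1)),
    paste0("P3\taromatic\t", c("phenylalanine", "tyrosine", "tryptophan"),
           "\t", c(0.6, 0.3, 0.1)),
    paste0("P4\turea\t", c("ornithine", "citrulline", "arginine", "urea",
                           "aspartate", "fumarate2", "x1", "x2"), "\t1")
  )
  writeLines(lines, path)
  read_pathway_library(path)
}

test_that("hypergeometric p-values equal combinatorial enumeration", {
  # frozen pocket cases
  expect_equal(phyper(5 - 1, 5, 15, 5, lower.tail = FALSE), 1 / choose(20, 5))
  lib <- toy_library()
  # exhaustive check of the tail formula against the enumeration oracle
  for (N in c(8, 10, 12)) {
    for (K in 1:(N - 1)) {
      for (n in 1:(N - 1)) {
        for (k in 0:min(K, n)) {
          expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                       hyper_oracle(k, N, K, n), tolerance = 1e-12)
        }
      }
    }
  }
  # monotone decreasing in k at fixed (N, K, n)
  ps <- vapply(0:4, function(k) hyper_oracle(k, 12, 5, 6), 0)
  expect_true(all(diff(ps) < 0))
})

test_that("enrichment of a fully-contained pathway is detected", {
  lib <- toy_library()
  res <- hypergeometric_enrich(
    c("Glucose", "lactate", "Pyruvate", "PEP", "F16BP"), lib,
    impact_min = -Inf
  )
  gly <- res[res$pathway_id == "P1", ]
  N <- length(lib$universe); n <- 5
  expect_equal(gly$k_matched, 5)
  expect_equal(gly$p_value, hyper_oracle(5, N, 5, n), tolerance = 1e-12)
  expect_equal(gly$impact, 1)
  # k = 0 pathways have p = 1 and impact 0
  tca <- res[res$pathway_id == "P2", ]
  expect_equal(tca$p_value, 1)
  expect_equal(tca$impact, 0)
  # BH across pathways uses the shared implementation
  expect_equal(res$q_value, benjamini_hochberg(res$p_value))
})

test_that("impact score is the matched importance fraction", {
  imp <- c(a = 0.5, b = 0.3, c = 0.2)
  expect_equal(impact_score(c("a", "b"), imp), 0.8)
  expect_equal(impact_score(character(0), imp), 0)
  expect_equal(impact_score(names(imp), imp), 1)
  expect_error(impact_score("z", imp), "not in pathway")
  # default importance reduces impact to k / K
  lib <- toy_library()
  res <- hypergeometric_enrich(c("citrate", "malate"), lib, impact_min = -Inf)
  expect_equal(res$impact[res$pathway_id == "P2"], 2 / 4)
})

test_that("the impact filter removes low-impact pathways", {
  lib <- toy_library()
  res <- hypergeometric_enrich(c("tryptophan"), lib, impact_min = 0.11)
  expect_false("P3" %in% res$pathway_id) # impact 0.1 <= 0.11 filtered
  res2 <- hypergeometric_enrich(c("tryptophan"), lib, impact_min = 0.05)
  expect_true("P3" %in% res2$pathway_id)
})

test_that("names are canonicalised and synonyms applied; misses warn", {
  lib <- toy_library()
  syn <- tibble::tibble(from = "grape sugar", to = "glucose")
  res <- hypergeometric_enrich(c("Grape-Sugar!"), lib, synonyms = syn,
                               impact_min = -Inf)
  expect_equal(res$k_matched[res$pathway_id == "P1"], 1)
  expect_warning(
    out <- hypergeometric_enrich(c("nonexistent"), lib, impact_min = -Inf),
    "No query metabolite"
  )
  expect_true(all(out$p_value == 1))
})

test_that("the shipped synthetic library loads and validates", {
  lib <- read_pathway_library(
    system.file("extdata", "synthetic_pathways.tsv", package = "metabnet")
  )
  expect_s3_class(lib, "pathway_library")
  expect_equal(nrow(lib$pathways), 15)
  expect_true(all(vapply(lib$pathways$importance, sum, 0) > 0))
})
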