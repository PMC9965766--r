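test_that("wide CSV round-trip is the identity", {
  ab <- tiny_abundance()
  path <- withr::local_tempfile(fileext = ".csv")
  write_abundance(ab, path)
  back <- read_abundance(path)
  expect_identical(back$sample_id, ab$sample_id)
  expect_identical(back$group, ab$group)
  expect_identical(abundance_matrix(back), abundance_matrix(as_abundance(ab)))

  # identity example: all-ones 2x2 table
  ones <- tibble::tibble(sample_id = c("s1", "s2"), group = c("CRC", "CTR"),
                         m1 = c(1, 1), m2 = c(1, 1))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_abundance(ones, p2)
  expect_equal(unname(abundance_matrix(read_abundance(p2))),
               matrix(1, 2, 2))
})

test_that("simulated cohort survives a write/read round trip bit-for-bit", {
  ab <- simulate_abundance(null_design(n_a = 10, n_b = 10, p = 5, seed = 42))
  path <- withr::local_tempfile(fileext = ".csv")
  write_abundance(ab, path)
  back <- read_abundance(path, aliases = NULL)
  expect_equal(abundance_matrix(back), abundance_matrix(ab), tolerance = 0)
})

test_that("reader rejects malformed tables with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,m1", "s1,CRC,1", "s1,CTR,2"), path)
  expect_error(read_abundance(path), "Duplicate sample")

  writeLines(c("sample_id,group,m1", "s1,CRC,1", "s2,CTR,oops"), path)
  expect_error(read_abundance(path), "oops.*m1|m1.*oops")

  writeLines(c("sample_id,group,m1", "s1,CRC,1", "s2,Martian,2"), path)
  expect_error(read_abundance(path), "Unknown group.*Martian|Martian")

  writeLines(c("sample_id,group,m1,m1", "s1,CRC,1,2"), path)
  expect_error(read_abundance(path), "Duplicate metabolite")
})

test_that("group aliases canonicalise case-insensitively", {
  expect_equal(canonicalize_groups(c("control", "Healthy", "crc", "Polyposis")),
               c("CTR", "CTR", "CRC", "PP"))
  expect_error(canonicalize_groups("unknown"), "Allowed")
})

test_that("mwtab flat block is parsed into samples x metabolites", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "#METABOLITE_DATA",
    "MS_METABOLITE_DATA_START",
    "Samples\ts1\ts2\ts3",
    "Factors\tDiagnosis:CRC\tDiagnosis:control\tDiagnosis:CRC",
    "glucose\t1.5\t2.5\t3.5",
    "lactate\t4\t5\t6",
    "MS_METABOLITE_DATA_END"
  ), path)
  ab <- read_abundance(path, format = "mwtab_flat")
  expect_equal(ab$group, c("CRC", "CTR", "CRC"))
  expect_equal(metabolite_names(ab), c("glucose", "lactate"))
  expect_equal(ab$glucose, c(1.5, 2.5, 3.5))
})

test_that("missing values are flagged, imputed by half-minimum, and capped", {
  ab <- tibble::tibble(
    sample_id = sprintf("s%d", 1:20),
    group = rep(c("CRC", "CTR"), each = 10),
    m1 = c(NA, 2:20), # 10% missing in CRC
    m2 = 21:40
  )
  imp <- impute_missing(ab)
  expect_equal(imp$m1[1], 1) # half of min positive (2)
  expect_false(anyNA(abundance_matrix(imp)))

  ab$m1[1:3] <- NA # 30% of CRC missing
  expect_error(impute_missing(ab), "missing in")
})

test_that("network round-trips preserve nodes, edges and weights", {
  nodes <- tibble::tibble(name = c("a", "b", "c"))
  edges <- tibble::tibble(
    from = c("a", "b", "a"), to = c("b", "c", "c"),
    weight = c(0.7, -0.8, 0.9), probability = c(0.99, 0.97, 1)
  )
  nodes$connectivity <- metabnet:::node_connectivity_from_edges(nodes$name, edges)
  net <- metabnet:::new_assoc_network(nodes, edges, 0.95, 0.6)

  for (fmt in c("graphml", "edge_tsv")) {
    path <- withr::local_tempfile()
    write_network(net, path, fmt)
    back <- read_network(path, fmt)
    expect_setequal(back$nodes$name, net$nodes$name)
    key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
    expect_setequal(key(back$edges), key(net$edges))
    ord <- match(key(net$edges), key(back$edges))
    expect_equal(back$edges$weight[ord], net$edges$weight, tolerance = 1e-12)
    expect_equal(back$edges$probability[ord], net$edges$probability, tolerance = 1e-12)
  }
})

test_that("an empty network keeps its isolated nodes on disk", {
  nodes <- tibble::tibble(name = c("x", "y", "z"), connectivity = 0)
  net <- metabnet:::new_assoc_network(
    nodes, tibble::tibble(from = character(), to = character(),
                          weight = numeric(), probability = numeric()),
    0.95, 0.6
  )
  for (fmt in c("graphml", "edge_tsv")) {
    path <- withr::local_tempfile()
    write_network(net, path, fmt)
    back <- read_network(path, fmt)
    expect_setequal(back$nodes$name, c("x", "y", "z"))
    expect_equal(nrow(back$edges), 0)
  }
})

test_that("results tables are sorted, precise, and re-readable", {
  rows <- tibble::tibble(
    metabolite = c("b_met", "a_met"),
    pair = "CRC vs CTR",
    p_value = c(0.123456789, 1.23456789e-7)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(rows, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$metabolite, c("a_met", "b_met")) # deterministic order
  expect_equal(back$p_value, c(1.23456789e-7, 0.123456789), tolerance = 1e-6)

  empty <- rows[0, ]
  write_results_table(empty, path)
  expect_equal(length(readLines(path)), 1) # header only
})
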