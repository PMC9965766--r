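test_that("Spearman matrix handles monotone maps and the textbook example", {
  n <- 20
  ab <- tibble::tibble(
    sample_id = sprintf("s%d", 1:n), group = "A",
    x = seq_len(n) + 0.5,
    lin = 2 * (seq_len(n) + 0.5) + 7,
    cub = -(seq_len(n) + 0.5)^3
  )
  r <- spearman_matrix(ab)
  expect_equal(r["x", "lin"], 1)
  expect_equal(r["x", "cub"], -1)
  expect_equal(diag(r), setNames(rep(1, 3), c("x", "lin", "cub")))

  ab5 <- tibble::tibble(sample_id = sprintf("s%d", 1:5), group = "A",
                        a = c(1, 2, 3, 4, 5), b = c(3, 1, 2, 5, 4))
  expect_equal(spearman_matrix(ab5)["a", "b"], 0.6, tolerance = 1e-12)
})

test_that("Spearman matrix agrees with stats::cor and zeroes constants", {
  ab <- simulate_abundance(null_design(n_a = 30, n_b = 5, p = 8, seed = 1))
  r <- spearman_matrix(ab)
  ref <- cor(abundance_matrix(ab), method = "spearman")
  expect_equal(r, ref, tolerance = 1e-12)
  ab$flat <- 3
  expect_warning(r2 <- spearman_matrix(ab), "Constant")
  expect_equal(unname(r2["flat", "met_001"]), 0)
})

test_that("CLR filter matches its definition on pocket cases", {
  # all off-diagonal entries equal -> no edge stands out
  M <- matrix(0.5, 4, 4); diag(M) <- 0
  expect_equal(clr_filter(M), matrix(0, 4, 4))

  # one dominant association gets the strictly largest CLR score
  M3 <- matrix(c(0, 0.9, 0.1,
                 0.9, 0, 0.1,
                 0.1, 0.1, 0), 3, 3, byrow = TRUE)
  z <- clr_filter(M3)
  expect_gt(z[1, 2], max(z[1, 3], z[2, 3]))
  expect_equal(z, t(z))
  expect_equal(diag(z), rep(0, 3))
  expect_equal(z, r_clr(M3), tolerance = 1e-12)

  expect_error(clr_filter(matrix(c(0, -1, -1, 0), 2)), "non-negative")
})

test_that("CLR filter is equivariant under variable permutation", {
  M <- abs(cor(matrix(withr::with_seed(3, rnorm(200)), 20, 10),
               method = "spearman"))^2
  diag(M) <- 0
  perm <- withr::with_seed(4, sample(10))
  expect_equal(clr_filter(M[perm, perm]), clr_filter(M)[perm, perm],
               tolerance = 1e-12)
})

test_that("PCLRC with one iteration is binary; full-fraction run is the
           top-quantile of the full-data CLR", {
  ab <- simulate_abundance(two_group_design(n_a = 40, n_b = 5, p = 12, seed = 2))
  a <- ab[ab$group == "A", ]
  one <- pclrc_infer(a, n_iterations = 1, seed = 3)
  expect_true(all(one$P %in% c(0, 1)))

  full <- pclrc_infer(a, n_iterations = 3, subsample_fraction = 1,
                      retention_quantile = 0.3, seed = 5)
  expect_true(all(full$P %in% c(0, 1))) # no subsampling variability
  r <- spearman_matrix(a)
  m <- r^2; diag(m) <- 0
  expect_equal(unname(full$P), r_keep_mask(r_clr(m), 0.3))
})

test_that("PCLRC matches an independent pure-R implementation", {
  ab <- simulate_abundance(two_group_design(n_a = 30, n_b = 5, p = 10, seed = 7))
  a <- ab[ab$group == "A", ]
  fit <- suppressWarnings(
    pclrc_infer(a, n_iterations = 25, subsample_fraction = 0.75,
                retention_quantile = 0.30, seed = 11)
  )
  ref <- r_pclrc(abundance_matrix(a), 25, 0.75, 0.30, 11)
  expect_equal(unname(fit$P), ref, tolerance = 1e-12)
})

test_that("edge probabilities are invariant under monotone marginal maps", {
  ab <- simulate_abundance(two_group_design(n_a = 60, n_b = 5, p = 15, seed = 4))
  a <- ab[ab$group == "A", ]
  p1 <- pclrc_infer(a, n_iterations = 60, seed = 9)$P
  a_log <- a
  for (m in metabolite_names(a)) a_log[[m]] <- log(a_log[[m]])
  p2 <- pclrc_infer(a_log, n_iterations = 60, seed = 9)$P
  expect_equal(p1, p2, tolerance = 1e-12) # ranks identical, same subsamples
})

test_that("network thresholding respects both cutoffs and keeps all nodes", {
  ab <- simulate_abundance(two_group_design(n_a = 50, n_b = 5, p = 12,
                                            rho = 0.85, seed = 6))
  fit <- pclrc_infer(ab[ab$group == "A", ], n_iterations = 100, seed = 2)
  net <- build_network(fit, p_min = 0.9, r_min = 0.6)
  expect_equal(nrow(net$nodes), 12)
  if (nrow(net$edges) > 0) {
    expect_true(all(net$edges$probability >= 0.9))
    expect_true(all(abs(net$edges$weight) >= 0.6))
  }
  # impossible probability threshold empties the edge set
  expect_equal(nrow(build_network(fit, p_min = 1.01)$edges), 0)
  # floor thresholds give every positive-probability pair
  all_edges <- build_network(fit, p_min = 1e-9, r_min = 0)
  expect_equal(nrow(all_edges$edges), sum(fit$P[upper.tri(fit$P)] > 0))
})

test_that("a planted block is recovered with high edge probability", {
  d <- two_group_design(n_a = 80, n_b = 5, p = 25, rho = 0.8, block = 1:5,
                        seed = 10)
  fit <- pclrc_infer(simulate_abundance(d) |> dplyr::filter(group == "A"),
                     n_iterations = 100, seed = 1)
  within <- fit$P[1:5, 1:5][upper.tri(diag(5))]
  noise <- fit$P[6:25, 6:25][upper.tri(diag(20))]
  expect_gt(median(within), 0.9)
  expect_lt(median(noise), 0.3)
  net <- build_network(fit, p_min = 0.95, r_min = 0.6)
  key <- paste(net$edges$from, net$edges$to)
  block_names <- sprintf("met_%03d", 1:5)
  expect_true(all(net$edges$from %in% block_names &
                    net$edges$to %in% block_names))
})
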