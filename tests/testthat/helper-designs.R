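# Shared synthetic fixtures for the test suite.

two_group_design <- function(n_a = 60, n_b = 60, p = 30, rho = 0.8,
                             block = 1:5, delta_idx = integer(0), delta = 0,
                             seed = 1L) {
  blocks <- if (rho > 0) list(A = list(list(indices = block, rho = rho))) else list()
  shifts <- if (length(delta_idx) > 0) list(A = list(indices = delta_idx, delta = delta)) else list()
  synthetic_design(c(A = n_a, B = n_b), p, blocks = blocks, shifts = shifts,
                   seed = seed)
}

null_design <- function(n_a = 60, n_b = 60, p = 30, seed = 1L) {
  synthetic_design(c(A = n_a, B = n_b), p, seed = seed)
}

tiny_abundance <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    group = c("CRC", "CRC", "CRC", "CTR", "CTR", "CTR"),
    m1 = c(1, 2, 3, 4, 5, 6),
    m2 = c(2, 4, 8, 16, 32, 64)
  )
}
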