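# shared fixtures, all generated in code

# printed percentage cells of the 13-subgroup study table, frozen from the
# published unadjusted and adjusted columns (A, C, E per row)
printed_unadjusted <- matrix(c(
  18, 68, 14,  28, 61, 11,  68, 14, 18,  34, 51, 15,  76,  9, 15,
  46, 43, 11,  40, 24, 36,  32, 34, 34,  34, 36, 30,  44, 33, 23,
  54, 20, 26,  52, 23, 25,  35, 27, 38), ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("A", "C", "E")))

printed_adjusted <- matrix(c(
  22, 64, 14,  47, 42, 11,  82,  0, 18,  59, 26, 15,  85,  0, 15,
  89,  0, 11,  59,  5, 36,  41, 25, 34,  41, 29, 30,  59, 18, 23,
  74,  0, 26,  75,  0, 25,  42, 20, 38), ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("A", "C", "E")))

# deterministic miniature family table (complete families) for likelihood
# cross-checks
tiny_families <- function(n = 10, seed = 42) {
  set.seed(seed)
  R_mz <- dyad_correlation_matrix("MZ")
  R_dz <- dyad_correlation_matrix("DZ")
  sample_families_mvn(R_mz, R_dz, n_mz = ceiling(n / 2), n_dz = floor(n / 2),
                      missing_father = 0, missing_sibling = 0,
                      missing_mother = 0, seed = seed)
}

# study-shaped sample: reference dyad correlations, reference missingness
study_sample <- function(n_mz = 498, n_dz = 439, seed = 1) {
  sample_families_mvn(n_mz = n_mz, n_dz = n_dz, seed = seed)
}

expect_percent_equal <- function(est, printed) {
  expect_equal(unname(sign(est) * floor(abs(est) * 100 + 0.5)),
               unname(printed))
}
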