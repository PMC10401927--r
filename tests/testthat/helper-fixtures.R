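# Small fixtures shared across test files; everything is built in code.

toy_counts <- function() {
  m <- matrix(c(10, 5, 0,
                2, 8, 4,
                0, 1, 9,
                6, 6, 6), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
  count_table(m, group = c(s1 = "HC", s2 = "HC", s3 = "RRMS", s4 = "RRMS"))
}

# two disjoint term blocks; every sample uses exactly one block
block_table <- function(n_per_block = 6, depth = 500, seed = 42) {
  set.seed(seed)
  V <- 10
  counts <- matrix(0, 2 * n_per_block, V)
  for (i in seq_len(n_per_block)) {
    counts[i, 1:5] <- rmultinom(1, depth, rep(0.2, 5))
    counts[n_per_block + i, 6:10] <- rmultinom(1, depth, rep(0.2, 5))
  }
  dimnames(counts) <- list(sprintf("s%02d", seq_len(2 * n_per_block)),
                           paste0("g", seq_len(V)))
  count_table(counts)
}

# default small simulated cohort for fast tests
small_cohort <- function(K = 4, V = 40, seed = 5, D_per_group = 12,
                         effect_topic = NULL, effect = 1) {
  beta <- generate_topics(K, V, dominant_per_topic = 6, dominance = 0.9)
  a <- rep(0.8, K)
  a2 <- a
  if (!is.null(effect_topic)) a2[effect_topic] <- a[effect_topic] * effect
  generate_cohort(beta,
                  alpha_by_group = list(HC = a, RRMS = a2),
                  group_sizes = c(HC = D_per_group, RRMS = D_per_group),
                  depth_log_mean = log(1e4), depth_log_sd = 0.5,
                  seed = seed)
}

expect_rows_sum_to_one <- function(m, tol = 1e-8) {
  expect_true(all(abs(rowSums(m) - 1) < tol))
}
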