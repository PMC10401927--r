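test_that("generate_topics builds normalized blocks with bounded overlap", {
  b <- generate_topics(K = 2, V = 10, dominant_per_topic = 5,
                       dominance = 1.0)
  expect_rows_sum_to_one(b, 1e-12)
  expect_equal(sum(b[1, ] * b[2, ]), 0)

  b <- generate_topics(K = 10, V = 150, dominant_per_topic = 5,
                       dominance = 0.9)
  expect_rows_sum_to_one(b, 1e-12)
  # closed-form pairwise cosine of the block construction
  a <- 0.9 / 5; cc <- 0.1 / 145
  cos_closed <- (2 * 5 * a * cc + 140 * cc^2) / (5 * a^2 + 145 * cc^2)
  cm <- topic_cosine_matrix(b, b)
  off <- cm[upper.tri(cm)]
  expect_equal(max(abs(off - cos_closed)), 0, tolerance = 1e-10)
  expect_lt(max(off), 0.02)

  expect_identical(generate_topics(4, 40, seed = 3),
                   generate_topics(4, 40, seed = 3))
  expect_error(generate_topics(K = 5, V = 10, dominant_per_topic = 5),
               "disjoint")
})

test_that("generate_cohort follows the Dirichlet-multinomial process", {
  beta <- generate_topics(3, 30, dominant_per_topic = 8)
  sim <- generate_cohort(beta,
                         alpha_by_group = list(HC = c(1, 1, 1),
                                               RRMS = c(2, 1, 1)),
                         group_sizes = c(HC = 500, RRMS = 500),
                         seed = 6)
  tab <- sim$table; tr <- sim$truth
  expect_s3_class(tab, "count_table")
  expect_rows_sum_to_one(tr$theta_true, 1e-12)
  expect_true(all(library_sizes(tab) >= 100))

  # Dirichlet mean: doubling one concentration raises that topic's mean
  # proportion to 2/4 vs 1/3 in the other group
  m_hc <- colMeans(tr$theta_true[tr$group == "HC", ])
  m_ms <- colMeans(tr$theta_true[tr$group == "RRMS", ])
  expect_equal(unname(m_hc[1]), 1 / 3, tolerance = 0.05)
  expect_equal(unname(m_ms[1]), 1 / 2, tolerance = 0.05)

  # law of large numbers: grand composition ~= mean-theta x beta
  expected <- colSums(
    (tr$theta_true * library_sizes(tab)) %*% beta)
  observed <- colSums(tab$counts)
  expect_lt(max(abs(observed - expected) / sum(observed)), 5e-3)

  # determinism
  sim2 <- generate_cohort(beta,
                          alpha_by_group = list(HC = c(1, 1, 1),
                                                RRMS = c(2, 1, 1)),
                          group_sizes = c(HC = 500, RRMS = 500),
                          seed = 6)
  expect_identical(sim2$table$counts, tab$counts)
  expect_error(generate_cohort(beta,
                               alpha_by_group = list(HC = c(-1, 1, 1),
                                                     RRMS = c(1, 1, 1)),
                               group_sizes = c(HC = 5, RRMS = 5)),
               "positive")
})

test_that("paired cohorts encode the jitter and vocabulary overlap", {
  beta <- generate_topics(5, 60, dominant_per_topic = 8)
  # epsilon 0 and full overlap: true cross-cohort cosines are the identity
  pair <- generate_paired_cohorts(beta, epsilon = 0, vocab_overlap = 1,
                                  seed = 2)
  expect_equal(unname(diag(pair$true_cosine)), rep(1, 5), tolerance = 1e-12)

  # large epsilon decorrelates the diagonal
  pair2 <- generate_paired_cohorts(beta, epsilon = 50, vocab_overlap = 1,
                                   seed = 2)
  expect_lt(mean(diag(pair2$true_cosine)), 0.5)

  # recorded cosines are self-consistent with topic_cosine_matrix
  pair3 <- generate_paired_cohorts(beta, epsilon = 0.05,
                                   vocab_overlap = 0.8, seed = 3)
  expect_equal(pair3$true_cosine,
               topic_cosine_matrix(pair3$cohort_a$truth$beta_true,
                                   pair3$cohort_b$truth$beta_true))
  shared <- intersect(colnames(pair3$cohort_a$truth$beta_true),
                      colnames(pair3$cohort_b$truth$beta_true))
  expect_lt(length(shared), 60)
  expect_error(generate_paired_cohorts(beta, vocab_overlap = 0),
               "vocab_overlap")
})

test_that("evaluate_recovery is exact on injected truth and order-free", {
  beta <- generate_topics(4, 40, dominant_per_topic = 8)
  truth <- structure(list(beta_true = beta, theta_true = NULL,
                          group = NULL), class = "synthetic_truth")
  fake_model <- structure(list(beta = beta), class = "lda_model")
  rep1 <- evaluate_recovery(fake_model, truth)
  expect_equal(rep1$matches$cosine, rep(1, 4), tolerance = 1e-12)
  expect_equal(rep1$fraction_matched, 1)

  shuffled <- structure(list(beta = beta[c(3, 1, 4, 2), ]),
                        class = "lda_model")
  rep2 <- evaluate_recovery(shuffled, truth)
  expect_equal(sort(rep2$matches$true_topic), sort(rep1$matches$true_topic))
  expect_equal(rep2$matches$cosine, rep(1, 4), tolerance = 1e-12)

  # K mismatch is reported, not an error
  sub <- structure(list(beta = beta[1:3, ]), class = "lda_model")
  rep3 <- evaluate_recovery(sub, truth)
  expect_identical(rep3$k_fitted, 3L)
  expect_identical(rep3$k_true, 4L)
  expect_identical(nrow(rep3$matches), 3L)
})
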