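test_that("assign_reads distributes library sizes by gamma", {
  sim <- small_cohort(seed = 12)
  fit <- fit_lda(sim$table, K = 4, seed = 1)
  ta <- assign_reads(fit, sim$table)
  libs <- library_sizes(sim$table)
  expect_equal(rowSums(ta$values), libs, tolerance = 1e-6)
  expect_true(all(ta$values >= 0))
  expect_identical(ta$group, sim$table$group)
  # direct product on one row
  d <- sample_ids <- rownames(ta$values)[1]
  expect_equal(ta$values[d, ], fit$gamma_norm[d, ] * libs[[d]])

  # largest-remainder rounding keeps integer row sums exact
  ta_int <- assign_reads(fit, sim$table, round = "largest_remainder")
  expect_true(all(ta_int$values == floor(ta_int$values)))
  expect_equal(rowSums(ta_int$values), libs)

  other <- subset_table(sim$table, samples = 1:5)
  expect_error(assign_reads(fit, other), "sample sets differ")
})

test_that("topic_cosine_matrix aligns vocabularies on the union", {
  # hand-worked partial-overlap case
  a <- matrix(c(.6, .4), 1, 2, dimnames = list("t1", c("g1", "g2")))
  b <- matrix(c(.5, .5), 1, 2, dimnames = list("u1", c("g2", "g3")))
  expected <- (.4 * .5) / (sqrt(.6^2 + .4^2) * sqrt(.5^2 + .5^2))
  expect_equal(topic_cosine_matrix(a, b)[1, 1], expected,
               tolerance = 1e-12)

  beta <- generate_topics(4, 30, dominant_per_topic = 6)
  expect_equal(unname(diag(topic_cosine_matrix(beta, beta))), rep(1, 4),
               tolerance = 1e-12)

  # disjoint support and disjoint vocabularies
  d1 <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
               dimnames = list(c("t1", "t2"), c("g1", "g2")))
  expect_equal(topic_cosine_matrix(d1, d1)[1, 2], 0)
  d2 <- d1; colnames(d2) <- c("h1", "h2")
  expect_warning(cm <- topic_cosine_matrix(d1, d2), "no genera")
  expect_true(all(cm == 0))

  # invariance to vocabulary order and zero-padding
  perm <- beta[, sample(ncol(beta))]
  pad <- cbind(beta, extra = 0)
  expect_equal(topic_cosine_matrix(beta, perm),
               topic_cosine_matrix(beta, beta), tolerance = 1e-12)
  expect_equal(topic_cosine_matrix(beta, pad),
               topic_cosine_matrix(beta, beta), tolerance = 1e-12)
})

test_that("match_topics keeps all pairs at or above the threshold", {
  cm <- matrix(c(0.92, 0.10,
                 0.86, 0.79,
                 0.81, 0.80), 3, 2, byrow = TRUE,
               dimnames = list(paste0("chen_", 1:3), paste0("yadav_", 1:2)))
  m <- match_topics(cm, threshold = 0.80)
  # 0.80 retained, 0.79 excluded; many-to-many: three matches to column 1
  expect_identical(nrow(m), 4L)
  expect_true(all(m$cosine >= 0.80))
  expect_false(any(m$topic_b == "yadav_2" & m$cosine < 0.80))
  expect_identical(sum(m$topic_b == "yadav_1"), 3L)
  expect_identical(m$cosine, sort(m$cosine, decreasing = TRUE))

  expect_identical(nrow(match_topics(cm, threshold = 1)), 0L)
  expect_identical(nrow(match_topics(cm, threshold = 1e-9)), 6L)
  expect_error(match_topics(cm, threshold = 0), "\\(0, 1\\]")
})

test_that("top_terms truncation rules behave as documented", {
  beta <- matrix(c(.5, .3, .15, .05), 1, 4,
                 dimnames = list("topic_1", c("a", "b", "c", "d")))
  model <- structure(list(beta = beta), class = "lda_model")
  expect_identical(top_terms(model, "topic_1", cutoff = 0.95)$genus,
                   c("a", "b", "c"))
  expect_identical(top_terms(model, "topic_1", rule = "top_n",
                             cutoff = 10)$genus, c("a", "b", "c", "d"))
  expect_identical(top_terms(model, "topic_1", rule = "floor",
                             cutoff = 0.2)$genus, c("a", "b"))
  # alphabetical tie-break
  beta2 <- matrix(c(.4, .4, .2), 1, 3,
                  dimnames = list("t", c("zeta", "alpha", "mid")))
  model2 <- structure(list(beta = beta2), class = "lda_model")
  expect_identical(top_terms(model2, "t", rule = "top_n", cutoff = 2)$genus,
                   c("alpha", "zeta"))
})
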