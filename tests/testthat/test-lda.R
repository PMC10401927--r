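test_that("e_step matches the scalar fixed-point oracle and closed forms", {
  # degenerate beta forces assignment
  es <- e_step(c(10, 0), matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE),
               alpha = 1)
  expect_equal(es$phi_d[1, ], c(1, 0))
  expect_equal(es$gamma_d, c(11, 1))

  # identical rows give symmetric responsibilities
  beta_sym <- matrix(c(.3, .5, .2, .3, .5, .2), 2, 3, byrow = TRUE)
  es <- e_step(c(4, 1, 2), beta_sym, alpha = 0.7)
  expect_true(all(abs(es$phi_d - 0.5) < 1e-10))

  # worked 2-topic / 3-term case against the oracle
  beta <- matrix(c(.7, .2, .1,
                   .1, .2, .7), 2, 3, byrow = TRUE)
  n <- c(3, 1, 2)
  es <- e_step(n, beta, alpha = 0.5, tol = 1e-14, max_iter = 10000)
  expect_equal(es$gamma_d, oracle_e_step(n, beta, 0.5), tolerance = 1e-10)

  # phi rows sum to one; gamma >= alpha
  expect_true(all(abs(rowSums(es$phi_d) - 1) < 1e-10))
  expect_true(all(es$gamma_d >= 0.5))

  expect_error(e_step(c(1, 1), matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE),
                      alpha = 1), "zero probability")
})

test_that("estimate_alpha solves the symmetric stationary condition", {
  # all gammas equal (c, ..., c): stationary alpha satisfies
  # digamma(K a) - digamma(a) = digamma(K c) - digamma(c)  =>  a = c
  K <- 4; cc <- 2.5
  gm <- matrix(cc, 10, K)
  target <- digamma(K * cc) - digamma(cc)
  root <- uniroot(function(a) digamma(K * a) - digamma(a) - target,
                  c(1e-6, 100), tol = 1e-12)$root
  a_hat <- estimate_alpha(gm, alpha = 1)
  expect_equal(a_hat, root, tolerance = 1e-8)
  expect_equal(a_hat, cc, tolerance = 1e-6)

  # D = 1 degenerate and determinism
  one <- matrix(c(3, 1, 2), 1, 3)
  a1 <- estimate_alpha(one, alpha = 1)
  expect_true(is.finite(a1) && a1 > 0)
  expect_identical(a1, estimate_alpha(one, alpha = 1))
})

test_that("fit_lda recovers disjoint blocks and honors determinism", {
  tab <- block_table()
  fit <- fit_lda(tab, K = 2, seed = 1, n_starts = 2)
  expect_rows_sum_to_one(fit$beta)
  expect_rows_sum_to_one(fit$gamma_norm)
  block_mass <- rbind(rowSums(fit$beta[, 1:5]), rowSums(fit$beta[, 6:10]))
  expect_true(all(apply(block_mass, 2, max) >= 0.99))

  fit2 <- fit_lda(tab, K = 2, seed = 1, n_starts = 2)
  expect_identical(fit$beta, fit2$beta)
  expect_identical(fit$gamma_norm, fit2$gamma_norm)

  expect_error(fit_lda(tab, K = 50, seed = 1), "out of range")
})

test_that("K = 1 degenerates to smoothed pooled frequencies", {
  tab <- toy_counts()
  fit <- fit_lda(tab, K = 1, seed = 1, eta = 1e-8)
  pooled <- colSums(tab$counts) / sum(tab$counts)
  expect_equal(as.numeric(fit$beta), as.numeric(pooled), tolerance = 1e-6)
  expect_true(all(abs(fit$gamma_norm - 1) < 1e-12))

  # closed-form objective: multinomial log-likelihood + eta log prior
  ll <- sum(tab$counts %*% log(fit$beta[1, ])) +
    fit$eta * sum(log(fit$beta))
  expect_equal(elbo(fit, tab), ll, tolerance = 1e-6)
})

test_that("elbo recomputation matches the recorded trace", {
  sim <- small_cohort(seed = 21)
  fit <- fit_lda(sim$table, K = 4, seed = 2)
  expect_equal(elbo(fit, sim$table),
               fit$elbo_trace[length(fit$elbo_trace)], tolerance = 1e-6)
  bad <- sim$table
  colnames(bad$counts) <- rev(colnames(bad$counts))
  expect_error(elbo(fit, bad), "vocabulary")
})

test_that("ELBO is monotone and label-equivariant over random fits", {
  for (s in 1:5) {
    sim <- small_cohort(seed = 100 + s)
    fit <- fit_lda(sim$table, K = 3, seed = s)
    expect_true(all(diff(fit$elbo_trace) >= -1e-6))
  }

  # permuting samples permutes gamma rows; permuting vocab permutes beta
  # (for equivalent initializations, supplied explicitly)
  sim <- small_cohort(seed = 33)
  set.seed(8)
  init <- matrix(rgamma(3 * ncol(sim$table$counts), 1), 3)
  fit <- fit_lda(sim$table, K = 3, seed = 4, beta_init = init)
  ps <- sample(nrow(sim$table$counts))
  pv <- sample(ncol(sim$table$counts))
  perm <- count_table(sim$table$counts[ps, pv])
  fitp <- fit_lda(perm, K = 3, seed = 4, beta_init = init[, pv])
  expect_equal(unname(fitp$gamma_norm),
               unname(fit$gamma_norm[ps, ]), tolerance = 1e-6)
  expect_equal(unname(fitp$beta), unname(fit$beta[, pv]),
               tolerance = 1e-6)
})

test_that("fractional counts are accepted", {
  m <- toy_counts()$counts * 0.5 + 0.25
  fit <- fit_lda(count_table(m), K = 2, seed = 1)
  expect_rows_sum_to_one(fit$beta)
  expect_true(all(diff(fit$elbo_trace) >= -1e-6))
})
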