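# Independent oracles, written as plain scalar loops with no shared code
# with the package internals.

# per-document variational fixed point
oracle_e_step <- function(n, beta, alpha, iters = 10000, tol = 1e-14) {
  K <- nrow(beta); V <- ncol(beta)
  gamma <- rep(alpha + sum(n) / K, K)
  for (it in seq_len(iters)) {
    phi <- matrix(0, V, K)
    for (v in seq_len(V)) {
      for (k in seq_len(K))
        phi[v, k] <- beta[k, v] * exp(digamma(gamma[k]))
      if (sum(phi[v, ]) > 0) phi[v, ] <- phi[v, ] / sum(phi[v, ])
    }
    gnew <- rep(alpha, K)
    for (v in seq_len(V))
      for (k in seq_len(K))
        gnew[k] <- gnew[k] + n[v] * phi[v, k]
    if (max(abs(gnew - gamma)) < tol) return(gnew)
    gamma <- gnew
  }
  gamma
}

# brute-force mean pairwise cosine
oracle_caojuan <- function(beta) {
  K <- nrow(beta); acc <- 0; np <- 0
  for (i in seq_len(K - 1)) for (j in seq.int(i + 1, K)) {
    acc <- acc + sum(beta[i, ] * beta[j, ]) /
      (sqrt(sum(beta[i, ]^2)) * sqrt(sum(beta[j, ]^2)))
    np <- np + 1
  }
  acc / np
}

# step-up BH by enumeration
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    cand <- 1
    for (j in i:m) cand <- min(cand, m * ps[j] / j)
    qs[i] <- cand
  }
  out <- numeric(m)
  out[ord] <- qs
  out
}

# greedy one-to-one cosine matching between two topic sets (row matrices)
greedy_match_cosines <- function(a, b) {
  cm <- a %*% t(b) /
    (sqrt(rowSums(a^2)) %o% sqrt(rowSums(b^2)))
  out <- numeric(min(nrow(a), nrow(b)))
  for (i in seq_along(out)) {
    ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    out[i] <- cm[ij[1], ij[2]]
    cm[ij[1], ] <- -Inf
    cm[, ij[2]] <- -Inf
  }
  out
}
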