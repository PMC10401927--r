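#' Latent Dirichlet allocation by variational EM
#'
#' Fits the standard LDA model to a samples-x-genera count table, treating
#' each sample as a document and each genus as a term. Inference is
#' mean-field variational EM: a per-document Dirichlet `gamma` over topic
#' proportions and per-term multinomial responsibilities `phi`, alternated
#' with maximum a posteriori re-estimation of the topic-term matrix `beta`
#' (Dirichlet-smoothed by `eta`) and, optionally, Newton updates of the
#' symmetric Dirichlet concentration `alpha`.
#'
#' The objective recorded in `elbo_trace` is the evidence lower bound plus
#' the `eta` log-prior on `beta`; it is non-decreasing across EM iterations
#' up to the E-step tolerance. Fractional counts are accepted: the
#' multinomial likelihood generalizes by weighting, which is needed when
#' refitting on read-assigned topic tables.
#'
#' @param table a `count_table`; every sample total must be positive
#' @param K number of topics, `1 <= K < min(samples, features)`
#' @param seed integer seed; fits are bitwise reproducible for a fixed
#'   `(seed, n_starts, table, K)`
#' @param tol relative change in the objective below which EM stops
#' @param max_iter maximum EM iterations; hitting it records a
#'   non-convergence warning in the model rather than erroring
#' @param estimate_alpha update `alpha` each iteration (default) or keep
#'   it fixed at `alpha_init`
#' @param n_starts random restarts; the model with the best final
#'   objective is returned
#' @param alpha_init initial symmetric Dirichlet concentration
#' @param eta Dirichlet smoothing pseudo-mass on each topic-term cell,
#'   keeping all of `beta` strictly positive
#' @param e_tol,e_max_iter per-document E-step fixed-point tolerance (mean
#'   absolute change in `gamma`) and iteration cap
#' @param beta_init optional K x V matrix to start from (rows normalized
#'   internally); overrides the seeded random initialization and forces
#'   `n_starts = 1`
#' @return an object of class `lda_model` with elements `beta` (K x V,
#'   rows sum to 1), `gamma` (D x K variational Dirichlet parameters),
#'   `gamma_norm` (rows sum to 1), `alpha`, `elbo_trace`, `K`, `vocab`,
#'   `sample_ids`, `seed`, `converged`, `n_iter`
#' @export
fit_lda <- function(table, K, seed = 1L, tol = 1e-4, max_iter = 200L,
                    estimate_alpha = TRUE, n_starts = 1L,
                    alpha_init = 50 / K, eta = 0.1,
                    e_tol = 1e-8, e_max_iter = 100L, beta_init = NULL) {
  X <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  D <- nrow(X); V <- ncol(X)
  if (K < 1 || K >= min(D, V))
    stop(sprintf("K = %d out of range: need 1 <= K < min(D, V) = %d",
                 K, min(D, V)))
  if (any(rowSums(X) <= 0)) stop("every sample must have a positive total")

  old_rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_rng))
    assign(".Random.seed", old_rng, envir = globalenv()))

  if (!is.null(beta_init)) n_starts <- 1L
  best <- NULL
  for (s in seq_len(n_starts)) {
    set.seed(as.integer(seed) + (s - 1L) * 1000L)
    fit <- vem_one_start(X, K, tol, max_iter, estimate_alpha,
                         alpha_init, eta, e_tol, e_max_iter, beta_init)
    if (is.null(best) || fit$objective > best$objective) best <- fit
  }

  gamma <- best$gamma
  dimnames(gamma) <- list(rownames(X), paste0("topic_", seq_len(K)))
  beta <- best$beta
  dimnames(beta) <- list(paste0("topic_", seq_len(K)), colnames(X))
  structure(list(
    beta = beta,
    gamma = gamma,
    gamma_norm = gamma / rowSums(gamma),
    alpha = best$alpha,
    eta = eta,
    elbo_trace = best$trace,
    K = K,
    vocab = colnames(X),
    sample_ids = rownames(X),
    seed = as.integer(seed),
    n_starts = as.integer(n_starts),
    converged = best$converged,
    n_iter = length(best$trace)
  ), class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("lda_model: K = %d topics, %d samples, %d terms\n",
              x$K, length(x$sample_ids), length(x$vocab)))
  cat(sprintf("alpha = %.4g, objective = %.4f after %d iterations%s\n",
              x$alpha, x$elbo_trace[length(x$elbo_trace)], x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

# One VEM run from a random beta initialization. All documents are updated
# simultaneously: with Eg = exp(digamma(gamma)) the implicit responsibilities
# are phi[d,v,k] = Eg[d,k] beta[k,v] / Z[d,v], Z = Eg %*% beta, so the whole
# E-step fixed point reduces to two D x V / D x K matrix products per sweep.
vem_one_start <- function(X, K, tol, max_iter, estimate_alpha,
                          alpha, eta, e_tol, e_max_iter,
                          beta_init = NULL) {
  D <- nrow(X); V <- ncol(X)
  beta <- if (is.null(beta_init)) {
    matrix(stats::rgamma(K * V, shape = 1), K, V)
  } else {
    matrix(as.numeric(beta_init), K, V)
  }
  beta <- beta / rowSums(beta)
  gamma <- matrix(alpha + rowSums(X) / K, D, K)
  trace <- numeric(0)
  converged <- FALSE
  obj_prev <- -Inf

  for (iter in seq_len(max_iter)) {
    es <- batch_e_step(X, beta, alpha, gamma, e_tol, e_max_iter)
    gamma <- es$gamma
    obj <- elbo_terms(X, beta, alpha, eta, gamma, es$logZ)
    trace <- c(trace, obj)
    if (is.finite(obj_prev) &&
        abs(obj - obj_prev) / abs(obj_prev) < tol) {
      converged <- TRUE
      break
    }
    obj_prev <- obj

    # M-step: beta[k,v] proportional to eta + sum_d X[d,v] phi[d,v,k]
    beta_ss <- beta * (t(es$Eg) %*% es$R)
    beta <- (beta_ss + eta) / rowSums(beta_ss + eta)
    if (estimate_alpha)
      alpha <- update_alpha(gamma, alpha)
  }
  list(beta = beta, gamma = gamma, alpha = alpha, trace = trace,
       objective = trace[length(trace)], converged = converged)
}

# Fixed-point E-step over all documents at once; warm-started from the
# previous outer iteration's gamma so the objective stays monotone.
batch_e_step <- function(X, beta, alpha, gamma, e_tol, e_max_iter) {
  tbeta <- t(beta)
  for (i in seq_len(e_max_iter)) {
    Eg <- exp(digamma(gamma))
    Z <- Eg %*% beta
    if (any(Z[X > 0] <= 0))
      stop("term observed with zero probability under every topic")
    R <- X / Z
    R[X == 0] <- 0
    gamma_new <- alpha + Eg * (R %*% tbeta)
    delta <- max(rowMeans(abs(gamma_new - gamma)))
    gamma <- gamma_new
    if (delta < e_tol) break
  }
  Eg <- exp(digamma(gamma))
  Z <- Eg %*% beta
  R <- X / Z
  R[X == 0] <- 0
  list(gamma = gamma, Eg = Eg, R = R, logZ = log(Z))
}

# Objective: sum over documents of the per-document ELBO plus the eta
# log-prior on beta. The z/w terms collapse to sum_dv X[d,v] (log Z[d,v] -
# digamma(sum_k gamma[d,k])) because phi is the exact per-term posterior
# given gamma.
elbo_terms <- function(X, beta, alpha, eta, gamma, logZ) {
  K <- ncol(gamma)
  gsum <- rowSums(gamma)
  dg_sum <- digamma(gsum)
  Elog <- digamma(gamma) - dg_sum
  theta_prior <- nrow(X) * (lgamma(K * alpha) - K * lgamma(alpha)) +
    (alpha - 1) * sum(Elog)
  q_theta <- sum(lgamma(gsum)) - sum(lgamma(gamma)) +
    sum((gamma - 1) * Elog)
  words <- sum(X * logZ) - sum(rowSums(X) * dg_sum)
  theta_prior + words - q_theta + eta * sum(log(beta))
}

#' Variational E-step for a single document
#'
#' Runs the standard fixed point `phi[v,k] proportional-to beta[k,v] *
#' exp(digamma(gamma[k]))`, `gamma[k] = alpha + sum_v n_v phi[v,k]` for one
#' sample's count vector, holding the topic-term matrix fixed.
#'
#' @param doc_counts length-V non-negative count vector
#' @param beta K x V topic-term matrix with normalized rows
#' @param alpha positive symmetric Dirichlet concentration
#' @param tol convergence tolerance on the mean absolute change in `gamma`
#' @param max_iter iteration cap
#' @return list with `gamma_d` (length-K variational Dirichlet parameters),
#'   `phi_d` (V x K responsibilities; rows with zero counts are the
#'   posterior they would receive if observed), and `bound_d`, the
#'   document's contribution to the evidence lower bound
#' @export
e_step <- function(doc_counts, beta, alpha, tol = 1e-8, max_iter = 100L) {
  if (alpha <= 0) stop("alpha must be positive")
  K <- nrow(beta); V <- ncol(beta)
  n <- as.numeric(doc_counts)
  if (length(n) != V) stop("doc_counts length must match ncol(beta)")
  if (any(n < 0)) stop("doc_counts must be non-negative")
  gamma <- rep(alpha + sum(n) / K, K)
  for (i in seq_len(max_iter)) {
    w <- exp(digamma(gamma))          # length K
    phi_un <- t(beta) * rep(w, each = V) # V x K
    Z <- rowSums(phi_un)
    if (any(Z[n > 0] <= 0))
      stop("term observed with zero probability under every topic")
    phi <- phi_un / ifelse(Z > 0, Z, 1)
    gamma_new <- alpha + colSums(n * phi)
    if (mean(abs(gamma_new - gamma)) < tol) {
      gamma <- gamma_new
      break
    }
    gamma <- gamma_new
  }
  w <- exp(digamma(gamma))
  phi_un <- t(beta) * rep(w, each = V)
  Z <- rowSums(phi_un)
  phi <- phi_un / ifelse(Z > 0, Z, 1)
  dg_sum <- digamma(sum(gamma))
  Elog <- digamma(gamma) - dg_sum
  bound <- lgamma(K * alpha) - K * lgamma(alpha) + (alpha - 1) * sum(Elog) +
    sum(n * log(ifelse(Z > 0, Z, 1))) - sum(n) * dg_sum -
    (lgamma(sum(gamma)) - sum(lgamma(gamma)) + sum((gamma - 1) * Elog))
  list(gamma_d = gamma, phi_d = phi, bound_d = bound)
}

#' Newton update of the symmetric Dirichlet concentration
#'
#' Maximizes the symmetric-Dirichlet log likelihood of the expected
#' log-proportions implied by the variational parameters, with step-halving
#' to keep `alpha` positive and the objective non-decreasing.
#'
#' @param gammas D x K matrix of variational Dirichlet parameters
#' @param alpha current positive value
#' @param max_iter Newton iteration cap
#' @param tol convergence tolerance on the change in `alpha`
#' @return updated positive scalar
#' @export
estimate_alpha <- function(gammas, alpha, max_iter = 50L, tol = 1e-10) {
  update_alpha(as.matrix(gammas), alpha, max_iter, tol)
}

update_alpha <- function(gamma, alpha, max_iter = 50L, tol = 1e-10) {
  D <- nrow(gamma); K <- ncol(gamma)
  if (K < 2) return(alpha)  # single-topic likelihood is flat in alpha
  S <- sum(digamma(gamma) - digamma(rowSums(gamma)))
  obj <- function(a) D * (lgamma(K * a) - K * lgamma(a)) + (a - 1) * S
  f0 <- obj(alpha)
  for (i in seq_len(max_iter)) {
    g <- D * K * (digamma(K * alpha) - digamma(alpha)) + S
    h <- D * K * (K * trigamma(K * alpha) - trigamma(alpha))
    step <- g / h
    a_new <- alpha - step
    halvings <- 0
    while ((a_new <= 0 || obj(a_new) < f0) && halvings < 30) {
      step <- step / 2
      a_new <- alpha - step
      halvings <- halvings + 1
    }
    if (a_new <= 0 || obj(a_new) < f0) break
    moved <- abs(a_new - alpha)
    alpha <- a_new
    f0 <- obj(alpha)
    if (moved < tol) break
  }
  alpha
}

#' Evidence lower bound of a fitted model on a table
#'
#' Recomputes the recorded objective (per-document bounds plus the prior
#' terms on `alpha` and `beta`) from the model's stored variational state,
#' matching the final entry of `elbo_trace`.
#'
#' @param model an `lda_model`
#' @param table the `count_table` the model was fitted on (vocabulary must
#'   match; extra all-zero samples contribute nothing)
#' @return a scalar
#' @export
elbo <- function(model, table) {
  X <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  if (!identical(colnames(X), model$vocab))
    stop("table features do not match model vocabulary")
  keep <- rowSums(X) > 0
  X <- X[keep, , drop = FALSE]
  if (!all(rownames(X) %in% rownames(model$gamma)))
    stop("table samples do not match model samples")
  gamma <- model$gamma[rownames(X), , drop = FALSE]
  Eg <- exp(digamma(gamma))
  Z <- Eg %*% model$beta
  elbo_terms(X, model$beta, model$alpha, model$eta, gamma, log(Z))
}
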