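#' Block-structured topic-term matrix
#'
#' Each topic concentrates `dominance` of its probability mass uniformly on
#' its own disjoint block of `dominant_per_topic` genera and spreads the
#' remaining mass uniformly over all other genera. With disjoint blocks the
#' pairwise topic cosine has a closed form and is small for realistic
#' dominance, giving well-separated ground-truth communities.
#'
#' @param K number of topics
#' @param V vocabulary size (number of genera); needs
#'   `K * dominant_per_topic <= V`
#' @param dominant_per_topic genera per block
#' @param dominance total mass on the block, in `(0, 1]`
#' @param seed integer seed (only used for genus naming order stability;
#'   the construction itself is deterministic)
#' @return K x V matrix with rows summing to 1; genus names `g001...`
#' @export
generate_topics <- function(K, V, dominant_per_topic = 5, dominance = 0.9,
                            seed = 1L) {
  b <- dominant_per_topic
  if (K * b > V)
    stop("K * dominant_per_topic exceeds V; blocks cannot be disjoint")
  beta <- matrix(0, K, V)
  for (k in seq_len(K)) {
    block <- ((k - 1) * b + 1):(k * b)
    beta[k, block] <- dominance / b
    beta[k, -block] <- (1 - dominance) / (V - b)
  }
  dimnames(beta) <- list(paste0("topic_", seq_len(K)),
                         sprintf("g%03d", seq_len(V)))
  beta
}

#' Simulate one cohort from the LDA generative process
#'
#' Per sample: topic proportions `theta ~ Dirichlet(alpha)` of the
#' sample's group, a library size from a log-normal (rounded, floored at
#' 100), and counts from `Multinomial(library, theta' beta_true)`. Group
#' effects are encoded in the Dirichlet concentrations so the simulator's
#' family matches the fitted model's.
#'
#' Defaults mirror a small 16S cohort: two groups of 20 samples,
#' library sizes spanning roughly 1e3-1e5 reads.
#'
#' @param beta_true K x V topic-term matrix (e.g. [generate_topics()])
#' @param alpha_by_group named list mapping each group level to a positive
#'   length-K concentration vector
#' @param group_sizes named integer vector of samples per group
#' @param depth_log_mean,depth_log_sd log-normal library-size parameters
#' @param seed integer seed; identical seeds give identical output
#' @return list with `table` (a `count_table` with group labels) and
#'   `truth` (class `synthetic_truth`: `beta_true`, `theta_true`, `group`,
#'   `alpha_by_group`, `depths`, `seed`)
#' @export
generate_cohort <- function(beta_true,
                            alpha_by_group = list(HC = rep(0.8, nrow(beta_true)),
                                                  RRMS = rep(0.8, nrow(beta_true))),
                            group_sizes = c(HC = 20, RRMS = 20),
                            depth_log_mean = log(2e4),
                            depth_log_sd = 0.7,
                            seed = 1L) {
  K <- nrow(beta_true); V <- ncol(beta_true)
  if (!setequal(names(alpha_by_group), names(group_sizes)))
    stop("alpha_by_group and group_sizes must name the same groups")
  if (any(unlist(alpha_by_group) <= 0))
    stop("Dirichlet concentrations must be positive")
  old_rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_rng))
    assign(".Random.seed", old_rng, envir = globalenv()))
  set.seed(as.integer(seed))

  group <- rep(names(group_sizes), times = group_sizes)
  D <- length(group)
  theta <- matrix(0, D, K)
  for (d in seq_len(D))
    theta[d, ] <- rdirichlet(alpha_by_group[[group[d]]])
  depths <- pmax(round(stats::rlnorm(D, depth_log_mean, depth_log_sd)), 100)
  probs <- theta %*% beta_true                   # D x V sample compositions
  counts <- matrix(0, D, V)
  for (d in seq_len(D))
    counts[d, ] <- stats::rmultinom(1, depths[d], probs[d, ])
  ids <- sprintf("s%03d", seq_len(D))
  dimnames(counts) <- list(ids, colnames(beta_true))
  rownames(theta) <- ids
  colnames(theta) <- rownames(beta_true)
  names(group) <- ids
  truth <- structure(list(beta_true = beta_true, theta_true = theta,
                          group = group, alpha_by_group = alpha_by_group,
                          depths = stats::setNames(depths, ids),
                          seed = as.integer(seed)),
                     class = "synthetic_truth")
  list(table = count_table(counts, group = group), truth = truth)
}

rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1  # numerically tiny shapes
  x / sum(x)
}

#' Simulate an exploratory/validation cohort pair
#'
#' Cohort A uses `beta_true` directly; cohort B's topics are
#' Dirichlet-jittered copies (`beta_B[k, ] ~ Dirichlet(beta_A[k, ] /
#' epsilon)`, so `epsilon = 0` copies exactly and large `epsilon`
#' decorrelates). A fraction `1 - vocab_overlap` of each cohort's genera is
#' renamed to cohort-private labels, emulating partially overlapping genus
#' vocabularies across studies. The true cross-cohort topic cosines (on the
#' renamed vocabularies) are recorded for validation of the matching logic.
#'
#' @param beta_true shared K x V topic-term matrix
#' @param epsilon non-negative jitter scale for cohort B's topics
#' @param alpha_by_group,group_sizes,depth_log_mean,depth_log_sd passed to
#'   [generate_cohort()] for both cohorts
#' @param vocab_overlap fraction of genera shared by name, in `(0, 1]`
#' @param seed integer seed
#' @return list with `cohort_a`, `cohort_b` (each as [generate_cohort()]),
#'   and `true_cosine` (K x K cross-cohort cosine matrix of the truths)
#' @export
generate_paired_cohorts <- function(beta_true, epsilon = 0.01,
                                    alpha_by_group = list(HC = rep(0.8, nrow(beta_true)),
                                                          RRMS = rep(0.8, nrow(beta_true))),
                                    group_sizes = c(HC = 20, RRMS = 20),
                                    depth_log_mean = log(2e4),
                                    depth_log_sd = 0.7,
                                    vocab_overlap = 1,
                                    seed = 1L) {
  if (vocab_overlap <= 0 || vocab_overlap > 1)
    stop("vocab_overlap must be in (0, 1]")
  if (epsilon < 0) stop("epsilon must be non-negative")
  old_rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_rng))
    assign(".Random.seed", old_rng, envir = globalenv()))
  set.seed(as.integer(seed))

  V <- ncol(beta_true)
  beta_b <- beta_true
  if (epsilon > 0) {
    for (k in seq_len(nrow(beta_b)))
      beta_b[k, ] <- rdirichlet(pmax(beta_true[k, ], 1e-12) / epsilon)
  }
  # rename a disjoint slice of genera per cohort to private labels
  n_private <- round((1 - vocab_overlap) * V)
  vocab_a <- vocab_b <- colnames(beta_true)
  if (n_private > 0) {
    idx <- sample.int(V, min(2 * n_private, V))
    ia <- idx[seq_len(n_private)]
    ib <- idx[seq.int(length(idx) - n_private + 1, length(idx))]
    vocab_a[ia] <- paste0(vocab_a[ia], "_privA")
    vocab_b[ib] <- paste0(vocab_b[ib], "_privB")
  }
  beta_a <- beta_true; colnames(beta_a) <- vocab_a
  colnames(beta_b) <- vocab_b

  cohort_a <- generate_cohort(beta_a, alpha_by_group, group_sizes,
                              depth_log_mean, depth_log_sd,
                              seed = as.integer(seed) + 1L)
  cohort_b <- generate_cohort(beta_b, alpha_by_group, group_sizes,
                              depth_log_mean, depth_log_sd,
                              seed = as.integer(seed) + 2L)
  list(cohort_a = cohort_a, cohort_b = cohort_b,
       true_cosine = topic_cosine_matrix(beta_a, beta_b))
}

#' Compare a fitted model against the simulation truth
#'
#' Greedy one-to-one matching of fitted to true topics by cosine (largest
#' cosine first, each topic used once). Reports the matched cosine per true
#' topic, the fraction matched at or above `threshold`, and the Pearson
#' correlation between fitted topic proportions and true `theta` over the
#' matched topics.
#'
#' @param model an `lda_model`
#' @param truth a `synthetic_truth`
#' @param threshold cosine needed to count a true topic as recovered
#' @return list with `matches` (data.frame `true_topic`, `fitted_topic`,
#'   `cosine`), `fraction_matched`, `mean_cosine`, `theta_correlation`
#' @export
evaluate_recovery <- function(model, truth, threshold = 0.80) {
  cm <- topic_cosine_matrix(model$beta, truth$beta_true)
  K_fit <- nrow(cm); K_true <- ncol(cm)
  avail_f <- rep(TRUE, K_fit); avail_t <- rep(TRUE, K_true)
  matches <- data.frame(true_topic = character(0),
                        fitted_topic = character(0), cosine = numeric(0),
                        stringsAsFactors = FALSE)
  for (i in seq_len(min(K_fit, K_true))) {
    sub <- cm
    sub[!avail_f, ] <- -Inf
    sub[, !avail_t] <- -Inf
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    matches <- rbind(matches, data.frame(
      true_topic = colnames(cm)[ij[2]],
      fitted_topic = rownames(cm)[ij[1]],
      cosine = cm[ij[1], ij[2]], stringsAsFactors = FALSE))
    avail_f[ij[1]] <- FALSE
    avail_t[ij[2]] <- FALSE
  }
  theta_cor <- NA_real_
  if (!is.null(truth$theta_true) &&
      all(rownames(model$gamma_norm) %in% rownames(truth$theta_true))) {
    g <- model$gamma_norm[, matches$fitted_topic, drop = FALSE]
    th <- truth$theta_true[rownames(g), matches$true_topic, drop = FALSE]
    theta_cor <- stats::cor(as.numeric(g), as.numeric(th))
  }
  list(matches = matches,
       fraction_matched = mean(matches$cosine >= threshold),
       mean_cosine = mean(matches$cosine),
       theta_correlation = theta_cor,
       k_fitted = K_fit, k_true = K_true)
}
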