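#' CaoJuan2009 topic-density metric
#'
#' Mean pairwise cosine similarity among the topic-term rows of `beta`.
#' Lower values mean more distinct topics; the metric is minimized over a
#' grid of topic numbers.
#'
#' @param beta K x V topic-term matrix, rows normalized, K >= 2
#' @return scalar in `[0, 1]`
#' @export
caojuan_metric <- function(beta) {
  K <- nrow(beta)
  if (K < 2) stop("caojuan_metric requires at least 2 topics")
  norms <- sqrt(rowSums(beta^2))
  cosmat <- (beta %*% t(beta)) / (norms %o% norms)
  sum(cosmat[upper.tri(cosmat)]) / (K * (K - 1) / 2)
}

#' Arun2010 divergence metric
#'
#' Symmetric Kullback-Leibler divergence between (i) the singular values of
#' the topic-term matrix and (ii) the document-length-weighted aggregate
#' topic distribution, each normalized to sum 1. Zero entries are floored
#' at `1e-12` before the logs. Lower is better; minimized over K.
#'
#' @param beta K x V topic-term matrix
#' @param gamma_norm D x K matrix of per-sample topic proportions
#' @param doc_lengths length-D positive vector of library sizes
#' @return non-negative scalar
#' @export
arun_metric <- function(beta, gamma_norm, doc_lengths) {
  K <- nrow(beta)
  if (K > min(nrow(gamma_norm), ncol(beta)))
    stop("K must not exceed min(D, V)")
  c1 <- svd(beta, nu = 0, nv = 0)$d
  c1 <- c1 / sum(c1)
  c2 <- as.numeric(doc_lengths %*% gamma_norm)
  c2 <- c2 / sum(c2)
  c1 <- pmax(c1, 1e-12)
  c2 <- pmax(c2, 1e-12)
  sum(c1 * (log(c1) - log(c2))) + sum(c2 * (log(c2) - log(c1)))
}

#' Choose the number of topics over a grid
#'
#' Fits LDA at every K of `k_grid` on each supplied table, evaluates the
#' CaoJuan2009 and Arun2010 metrics, takes the per-table per-metric argmin
#' (smallest K on ties), and averages those argmins; the rounded mean
#' (round-half-to-even) is the chosen K. Every fit uses the same seed and
#' number of restarts so the curves are comparable.
#'
#' @param tables a `count_table` or list of them (one per cohort)
#' @param k_grid integer grid of candidate topic numbers, length >= 2
#' @param seed integer seed shared by all fits
#' @param n_starts restarts per fit
#' @param ... further arguments to [fit_lda()]
#' @return object of class `k_selection`: a list with `k_grid`, `metrics`
#'   (one data.frame per table with columns `K`, `caojuan`, `arun`),
#'   `best_k_per_metric`, and `chosen_k`
#' @export
select_topic_number <- function(tables, k_grid, seed = 1L, n_starts = 1L,
                                ...) {
  if (inherits(tables, "count_table")) tables <- list(tables)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(k_grid) < 2) stop("k_grid must contain at least 2 values")
  metrics <- vector("list", length(tables))
  best <- list()
  for (ti in seq_along(tables)) {
    tab <- tables[[ti]]
    cj <- ar <- numeric(length(k_grid))
    for (i in seq_along(k_grid)) {
      fit <- fit_lda(tab, K = k_grid[i], seed = seed, n_starts = n_starts,
                     ...)
      cj[i] <- caojuan_metric(fit$beta)
      ar[i] <- arun_metric(fit$beta, fit$gamma_norm, library_sizes(tab))
    }
    metrics[[ti]] <- data.frame(K = k_grid, caojuan = cj, arun = ar)
    # smallest K wins ties (which.min takes the first of a sorted grid)
    best[[paste0("caojuan_table", ti)]] <- k_grid[which.min(cj)]
    best[[paste0("arun_table", ti)]] <- k_grid[which.min(ar)]
  }
  chosen <- as.integer(round(mean(unlist(best))))
  structure(list(k_grid = k_grid, metrics = metrics,
                 best_k_per_metric = best, chosen_k = chosen),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("k_selection over K =", paste(range(x$k_grid), collapse = ".."), "\n")
  for (m in names(x$best_k_per_metric))
    cat(sprintf("  %s: argmin K = %d\n", m, x$best_k_per_metric[[m]]))
  cat("chosen K =", x$chosen_k, "\n")
  invisible(x)
}
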