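#' Winsorize a vector at an upper quantile
#'
#' Values above the empirical `upper_quantile` (type-7 quantile) are pulled
#' down to that quantile; the lower tail is untouched. Used per feature to
#' damp outlier counts before genus-level differential abundance.
#'
#' @param values numeric vector
#' @param upper_quantile quantile in `(0.5, 1]`; `1` is a no-op
#' @return winsorized vector
#' @export
winsorize <- function(values, upper_quantile = 0.97) {
  if (upper_quantile <= 0.5 || upper_quantile > 1)
    stop("upper_quantile must be in (0.5, 1]")
  cap <- stats::quantile(values, upper_quantile, names = FALSE, type = 7)
  pmin(values, cap)
}

#' Differential abundance with compositional bias correction
#'
#' A linear-models-for-differential-abundance procedure: per feature,
#' ordinary least squares of log2 relative abundance (after an optional
#' winsorization and a pseudocount) on the two-level group indicator. The
#' shared compositional bias — every log-ratio coefficient is shifted by
#' the unknown change in total load — is estimated as the mode of the
#' kernel density of the raw coefficients across features and subtracted.
#' Corrected effects are tested with the OLS t statistic and
#' Benjamini-Hochberg adjusted; a feature is called significant when both
#' `p <= p_max` and `q <= q_max` (boundaries inclusive).
#'
#' @param table a `count_table` or `topic_abundance` with a two-level group
#' @param group_key unused placeholder for tables carrying several labels;
#'   the table's `group` field is the contrast
#' @param winsorize cap each feature at `winsor_quantile` before the
#'   pseudocount (recommended for genus counts, off for topic tables)
#' @param pseudocount added to every cell before log-transforming
#' @param winsor_quantile upper quantile for winsorization
#' @param reference reference group level; default the alphabetically
#'   first, so effects are log2 fold changes of the other level over it
#' @param p_max,q_max dual significance thresholds (defaults 0.05 / 0.25)
#' @return object of class `da_result`: data.frame with columns `feature`,
#'   `effect_log2` (bias-corrected), `se`, `t`, `df`, `p`, `q`,
#'   `significant`, `degenerate`; run metadata in attributes
#'   (`bias`, `reference`, `levels`, `winsorized`, `pseudocount`)
#' @export
linda_fit <- function(table, group_key = "group", winsorize = FALSE,
                      pseudocount = 0.5, winsor_quantile = 0.97,
                      reference = NULL, p_max = 0.05, q_max = 0.25) {
  if (inherits(table, "topic_abundance")) table <- as_count_table(table)
  grp <- table$group
  if (is.null(grp)) stop("table has no group labels; attach metadata first")
  keep <- !is.na(grp)
  counts <- table$counts[keep, , drop = FALSE]
  grp <- grp[keep]
  levels <- sort(unique(grp))
  if (length(levels) != 2)
    stop(sprintf("group must have exactly 2 levels, found %d",
                 length(levels)))
  if (is.null(reference)) reference <- levels[1]
  if (!reference %in% levels) stop("reference is not a group level")
  other <- setdiff(levels, reference)
  n1 <- sum(grp == reference); n2 <- sum(grp == other)
  if (min(n1, n2) < 2) stop("each group needs at least 2 samples")
  x <- as.numeric(grp == other)

  if (winsorize)
    counts <- apply(counts, 2, winsorize,
                    upper_quantile = winsor_quantile)
  y <- counts + pseudocount
  y <- log2(y / rowSums(y))            # samples x features

  # vectorized two-group OLS per feature
  m1 <- colMeans(y[x == 0, , drop = FALSE])
  m2 <- colMeans(y[x == 1, , drop = FALSE])
  raw <- m2 - m1
  df <- n1 + n2 - 2
  ss <- colSums((y[x == 0, , drop = FALSE] -
                   rep(m1, each = n1))^2) +
        colSums((y[x == 1, , drop = FALSE] -
                   rep(m2, each = n2))^2)
  se <- sqrt(ss / df * (1 / n1 + 1 / n2))

  degenerate <- se <= .Machine$double.eps * 100
  if (ncol(counts) < 2) {
    bias <- raw                         # single feature: nothing to anchor on
    degenerate <- rep(TRUE, length(raw))
  } else {
    bias <- density_mode(raw)
  }
  effect <- raw - bias
  tstat <- ifelse(degenerate, 0, effect / ifelse(se > 0, se, Inf))
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(tstat), df))
  q <- benjamini_hochberg(p)
  out <- data.frame(feature = colnames(counts), effect_log2 = effect,
                    se = se, t = tstat, df = df, p = p, q = q,
                    significant = p <= p_max & q <= q_max,
                    degenerate = degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "bias") <- bias
  attr(out, "reference") <- reference
  attr(out, "levels") <- c(reference, other)
  attr(out, "winsorized") <- winsorize
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("da_result", "data.frame")
  out
}

# Mode of the kernel density of the raw coefficients; the dominant mass of
# non-differential features pins down the compositional shift.
density_mode <- function(x) {
  if (length(unique(x)) == 1) return(x[1])
  d <- stats::density(x)
  d$x[which.max(d$y)]
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up procedure: `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1,
#' returned in the original order.
#'
#' @param pvals vector of p-values in `[0, 1]`
#' @return vector of q-values
#' @export
benjamini_hochberg <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  ord <- order(pvals, decreasing = TRUE)
  q <- pmin(1, cummin(m / seq(m, 1) * pvals[ord]))
  q[order(ord)]
}

#' Re-apply the dual significance rule with new thresholds
#'
#' @param result a `da_result`
#' @param p_max,q_max inclusive thresholds on raw p and BH q
#' @return the result with its `significant` column recomputed
#' @export
call_significant <- function(result, p_max = 0.05, q_max = 0.25) {
  result$significant <- result$p <= p_max & result$q <= q_max
  result
}
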