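#' Spearman rank correlation with a t-approximation p-value
#'
#' Rho is the Pearson correlation of average (midrank) ranks; the two-sided
#' p-value comes from `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom. Constant vectors have no defined rank correlation and return
#' `NA` for both values.
#'
#' @param x,y paired numeric vectors, length >= 4
#' @return list with `rho` and `p`
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("need at least 4 paired observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(rho = NA_real_, p = NA_real_))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2))
}

#' Within-topic genus co-occurrence network
#'
#' All pairwise Spearman correlations among a topic's assigned genera,
#' computed on per-sample relative abundances to remove library-size
#' artifacts. Edges are retained where the (optionally BH-adjusted)
#' p-value passes `alpha`; edge weight is `|rho|`. Pairs involving a
#' constant genus are skipped and listed in attribute `"skipped"`.
#'
#' @param table a `count_table`
#' @param genera character vector of the topic's assigned genus names
#'   (e.g. from [top_terms()]); must be a subset of the table's features
#' @param alpha significance level on the edge p-values
#' @param adjust `"none"` (raw p, default) or `"BH"` across the topic's
#'   pairs
#' @return object of class `topic_network`: list with `nodes` and `edges`
#'   (data.frame `from`, `to`, `rho`, `p`, `q`, `weight`)
#' @export
topic_network <- function(table, genera, alpha = 0.05,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  missing <- setdiff(genera, feature_ids(table))
  if (length(missing) > 0)
    stop(sprintf("genera not in table: %s", paste(missing, collapse = ", ")))
  empty <- data.frame(from = character(0), to = character(0),
                      rho = numeric(0), p = numeric(0), q = numeric(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  if (length(genera) < 2) {
    warning("fewer than 2 genera; returning an empty network")
    return(structure(list(nodes = genera, edges = empty),
                     class = "topic_network"))
  }
  ra <- relative_abundance(table)[, genera, drop = FALSE]
  pairs <- utils::combn(genera, 2)
  rho <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    s <- spearman_cor(ra[, pairs[1, i]], ra[, pairs[2, i]])
    rho[i] <- s$rho; p[i] <- s$p
  }
  skipped <- is.na(rho)
  edges <- data.frame(from = pairs[1, ], to = pairs[2, ], rho = rho, p = p,
                      stringsAsFactors = FALSE)[!skipped, , drop = FALSE]
  edges$q <- if (nrow(edges) > 0) benjamini_hochberg(edges$p) else numeric(0)
  crit <- if (adjust == "BH") edges$q else edges$p
  edges <- edges[!is.na(crit) & crit <= alpha, , drop = FALSE]
  edges$weight <- abs(edges$rho)
  rownames(edges) <- NULL
  out <- structure(list(nodes = genera, edges = edges),
                   class = "topic_network")
  attr(out, "skipped") <- t(pairs[, skipped, drop = FALSE])
  out
}

#' @export
print.topic_network <- function(x, ...) {
  cat(sprintf("topic_network: %d nodes, %d significant edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a network edge list as TSV
#' @param network a `topic_network`
#' @param path destination
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
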