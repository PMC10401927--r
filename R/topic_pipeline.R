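#' Assign each sample's reads to topics
#'
#' Multiplies each sample's topic proportions (`gamma_norm` row) by its
#' library size, distributing the sample's read count across topics. Values
#' are fractional by default; `round = "largest_remainder"` rounds each row
#' to integers that still sum exactly to the library size.
#'
#' @param model an `lda_model` fitted on `table`
#' @param table the source `count_table` (same sample set)
#' @param round `"none"` (default) or `"largest_remainder"`
#' @return object of class `topic_abundance`: list with `values`
#'   (samples x topics), and the group labels carried over
#' @export
assign_reads <- function(model, table, round = c("none",
                                                 "largest_remainder")) {
  round <- match.arg(round)
  if (!setequal(model$sample_ids, sample_ids(table)) ||
      !identical(sort(model$sample_ids), sort(sample_ids(table))))
    stop("model and table sample sets differ")
  g <- model$gamma_norm[sample_ids(table), , drop = FALSE]
  vals <- g * library_sizes(table)
  if (round == "largest_remainder")
    vals <- t(apply(vals, 1, largest_remainder))
  dimnames(vals) <- list(sample_ids(table), rownames(model$beta))
  structure(list(values = vals, group = table$group),
            class = "topic_abundance")
}

largest_remainder <- function(x) {
  total <- round(sum(x))
  fl <- floor(x)
  short <- total - sum(fl)
  if (short > 0) {
    idx <- order(x - fl, decreasing = TRUE)[seq_len(short)]
    fl[idx] <- fl[idx] + 1
  }
  fl
}

#' @export
print.topic_abundance <- function(x, ...) {
  cat(sprintf("topic_abundance: %d samples x %d topics\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Convert a topic-abundance table to a count table
#'
#' Topics become the features, so the topic table can flow into the same
#' differential-abundance machinery as genus counts.
#' @param x a `topic_abundance`
#' @return a `count_table`
#' @export
as_count_table <- function(x) count_table(x$values, group = x$group)

#' Cosine similarity between two sets of topics
#'
#' Aligns the two vocabularies on the union of genus names, filling genera
#' absent from a model with probability zero (no renormalization), then
#' computes the cosine of every cross pair of topic-term rows.
#' `align = "intersection"` restricts to shared genera instead, for
#' sensitivity analysis.
#'
#' @param beta_a,beta_b topic-term matrices with genus names as colnames
#'   (e.g. `$beta` of two `lda_model`s)
#' @param align `"union"` (default) or `"intersection"`
#' @return K_a x K_b matrix of cosines in `[0, 1]`
#' @export
topic_cosine_matrix <- function(beta_a, beta_b,
                                align = c("union", "intersection")) {
  align <- match.arg(align)
  va <- colnames(beta_a); vb <- colnames(beta_b)
  if (is.null(va) || is.null(vb))
    stop("both beta matrices need genus names as colnames")
  if (length(intersect(va, vb)) == 0)
    warning("vocabularies share no genera; all cosines are 0")
  vocab <- if (align == "union") union(va, vb) else intersect(va, vb)
  pad <- function(beta, v) {
    out <- matrix(0, nrow(beta), length(vocab),
                  dimnames = list(rownames(beta), vocab))
    shared <- intersect(v, vocab)
    out[, shared] <- beta[, shared, drop = FALSE]
    out
  }
  a <- pad(beta_a, va); b <- pad(beta_b, vb)
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  cm <- (a %*% t(b)) / (pmax(na, .Machine$double.eps) %o%
                          pmax(nb, .Machine$double.eps))
  pmin(pmax(cm, 0), 1)
}

#' Retain topic pairs above a cosine threshold
#'
#' Every pair at or above the threshold is kept (many-to-many: several
#' topics of one cohort may match a single topic of the other), sorted by
#' descending cosine.
#'
#' @param cosine K_a x K_b cosine matrix, e.g. from
#'   [topic_cosine_matrix()]
#' @param threshold retention cutoff in `(0, 1]`; pairs with cosine
#'   `>= threshold` are matches. Default `0.80`.
#' @return data.frame with columns `topic_a`, `topic_b`, `cosine`
#' @export
match_topics <- function(cosine, threshold = 0.80) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  idx <- which(cosine >= threshold, arr.ind = TRUE)
  ra <- rownames(cosine); cb <- colnames(cosine)
  if (is.null(ra)) ra <- paste0("topic_", seq_len(nrow(cosine)))
  if (is.null(cb)) cb <- paste0("topic_", seq_len(ncol(cosine)))
  out <- data.frame(topic_a = ra[idx[, 1]], topic_b = cb[idx[, 2]],
                    cosine = cosine[idx], stringsAsFactors = FALSE)
  out[order(-out$cosine), , drop = FALSE]
}

#' Top genera of a topic
#'
#' Genera sorted by descending topic-term probability, truncated by one of
#' three rules: the smallest set covering `cutoff` cumulative probability
#' mass (default 0.95), all genera above a probability floor, or the top
#' N. Ties in probability are broken alphabetically.
#'
#' @param model an `lda_model`
#' @param topic topic row name or index
#' @param rule `"cumulative"`, `"floor"` or `"top_n"`
#' @param cutoff rule parameter: mass fraction, probability floor, or N
#' @return data.frame with columns `genus`, `probability`
#' @export
top_terms <- function(model, topic, rule = c("cumulative", "floor", "top_n"),
                      cutoff = 0.95) {
  rule <- match.arg(rule)
  row <- model$beta[topic, ]
  ord <- order(-row, names(row))
  p <- row[ord]
  n <- switch(rule,
    cumulative = which(cumsum(p) >= cutoff - 1e-12)[1],
    floor = sum(p >= cutoff),
    top_n = min(as.integer(cutoff), length(p)))
  if (is.na(n)) n <- length(p)
  idx <- seq_len(n)
  data.frame(genus = names(p)[idx], probability = unname(p[idx]),
             stringsAsFactors = FALSE)
}
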