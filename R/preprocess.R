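#' Remove low-prevalence features
#'
#' Features whose relative abundance falls below `threshold` are dropped.
#' The default basis is the overall relative abundance pooled across the
#' dataset (feature total divided by grand total); per-sample bases are
#' available for sensitivity analysis.
#'
#' @param table a `count_table`
#' @param threshold relative-abundance cutoff; features strictly below it
#'   are removed. Default `1e-5`.
#' @param basis `"overall"` (feature total / grand total, default),
#'   `"mean"` (mean per-sample relative abundance) or `"max"` (max
#'   per-sample relative abundance)
#' @return a `count_table` restricted to retained features, with the
#'   dropped feature IDs and their abundances in attribute `"removed"`
#' @export
filter_low_prevalence <- function(table, threshold = 1e-5,
                                  basis = c("overall", "mean", "max")) {
  basis <- match.arg(basis)
  counts <- table$counts
  grand <- sum(counts)
  if (grand <= 0) stop("grand total is zero; nothing to filter")
  ra <- switch(basis,
    overall = colSums(counts) / grand,
    mean = colMeans(counts / pmax(rowSums(counts), 1)),
    max = apply(counts / pmax(rowSums(counts), 1), 2, max))
  keep <- ra >= threshold
  out <- subset_table(table, features = which(keep))
  attr(out, "removed") <- data.frame(feature = colnames(counts)[!keep],
                                     relative_abundance = ra[!keep],
                                     row.names = NULL)
  out
}

#' Aggregate features to a taxonomic rank
#'
#' Counts of features sharing the same label at `rank` are summed; features
#' whose label is missing or empty are pooled under `"unclassified"`. Each
#' sample's total is conserved exactly.
#'
#' @param table a `count_table` whose features are e.g. ASV IDs
#' @param taxonomy data.frame of lineage labels, rownames = feature IDs
#'   (see [read_taxonomy()])
#' @param rank column of `taxonomy` to aggregate at (default `"genus"`)
#' @return a `count_table` with one feature per rank label
#' @export
aggregate_to_rank <- function(table, taxonomy, rank = "genus") {
  if (!rank %in% names(taxonomy))
    stop(sprintf("taxonomy has no rank column '%s'", rank))
  feats <- feature_ids(table)
  absent <- setdiff(feats, rownames(taxonomy))
  if (length(absent) > 0)
    stop(sprintf("feature(s) absent from taxonomy: %s",
                 paste(absent, collapse = ", ")))
  labels <- as.character(taxonomy[feats, rank])
  labels[is.na(labels) | labels == ""] <- "unclassified"
  groups <- factor(labels, levels = unique(labels))
  agg <- t(rowsum(t(table$counts), groups))
  colnames(agg) <- levels(groups)
  count_table(agg, group = table$group)
}

#' Per-sample relative abundances
#'
#' @param table a `count_table`
#' @return samples-x-features matrix whose rows each sum to 1
#' @export
relative_abundance <- function(table) {
  totals <- rowSums(table$counts)
  zero <- totals <= 0
  if (any(zero))
    stop(sprintf("sample(s) with zero total: %s",
                 paste(rownames(table$counts)[zero], collapse = ", ")))
  table$counts / totals
}
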