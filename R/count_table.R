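#' Construct a sample-by-feature count table
#'
#' The central data container: a numeric matrix of non-negative counts with
#' samples in rows and features (typically genera) in columns, plus an
#' optional per-sample group factor used by the differential-abundance stage.
#' Counts are stored as doubles so that downstream fractional tables (reads
#' assigned to topics) share the same container; integer input is preserved
#' exactly.
#'
#' @param counts numeric matrix, samples x features, with unique non-empty
#'   dimnames. No negative or missing entries.
#' @param group optional character/factor vector of per-sample group labels,
#'   either named by sample or in row order. `NA` allowed for samples never
#'   used in differential abundance.
#' @return an object of class `count_table`
#' @export
count_table <- function(counts, group = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample rownames and feature colnames")
  if (anyNA(counts)) stop("counts contains missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', feature '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (anyDuplicated(rownames(counts)))
    stop(sprintf("duplicated sample ID: '%s'",
                 rownames(counts)[duplicated(rownames(counts))][1]))
  if (anyDuplicated(colnames(counts)))
    stop(sprintf("duplicated feature ID: '%s'",
                 colnames(counts)[duplicated(colnames(counts))][1]))
  if (!is.null(group)) {
    if (!is.null(names(group))) {
      missing <- setdiff(rownames(counts), names(group))
      group <- as.character(group)[match(rownames(counts), names(group))]
    } else {
      if (length(group) != nrow(counts))
        stop("group must have one entry per sample")
      group <- as.character(group)
    }
    names(group) <- rownames(counts)
  }
  structure(list(counts = counts, group = group), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d features\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$group)) {
    tab <- table(x$group, useNA = "ifany")
    cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  cat(sprintf("total reads: %s\n", format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

sample_ids <- function(table) rownames(table$counts)
feature_ids <- function(table) colnames(table$counts)

#' Per-sample library sizes
#' @param table a `count_table`
#' @return named numeric vector of row sums
#' @export
library_sizes <- function(table) rowSums(table$counts)

#' Subset a count table by samples and/or features
#' @param table a `count_table`
#' @param samples,features index vectors (names, logical, or integer)
#' @return a `count_table`
#' @export
subset_table <- function(table, samples = NULL, features = NULL) {
  counts <- table$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(features)) counts <- counts[, features, drop = FALSE]
  count_table(counts, group = table$group[rownames(counts)])
}

#' Read a count table from TSV, CSV or BIOM
#'
#' @param path file path
#' @param format `"tsv"`, `"csv"` or `"biom"`; default guessed from the
#'   file extension
#' @param orientation `"samples"` if samples are in rows, `"features"` if
#'   features are in rows (the table is transposed on read)
#' @return a validated `count_table` in samples-x-features orientation
#' @export
read_count_table <- function(path,
                             format = c("auto", "tsv", "csv", "biom"),
                             orientation = c("samples", "features")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", biom = "biom", "tsv")
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the biomformat package is required to read BIOM files")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix") # features x samples in BIOM
    counts <- t(m)
    if (orientation == "features") counts <- t(counts)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            row.names = NULL, check.names = FALSE,
                            stringsAsFactors = FALSE, comment.char = "")
    ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
    bad <- !vapply(df, is.numeric, logical(1))
    if (any(bad))
      stop(sprintf("non-numeric column '%s' in %s",
                   names(df)[bad][1], path))
    counts <- as.matrix(df)
    rownames(counts) <- ids
    if (anyDuplicated(ids))
      stop(sprintf("duplicated ID in first column: '%s'",
                   ids[duplicated(ids)][1]))
    if (orientation == "features") counts <- t(counts)
  }
  count_table(counts)
}

#' Attach sample metadata and set the group label
#'
#' @param table a `count_table`
#' @param metadata data.frame with sample IDs in the first column or in
#'   rownames, or a named vector of group labels
#' @param group_key column of `metadata` holding the group label
#' @param drop_uncovered drop samples absent from `metadata` instead of
#'   raising an error
#' @return the table with its `group` field populated; sample order kept
#' @export
attach_metadata <- function(table, metadata, group_key = "group",
                            drop_uncovered = FALSE) {
  if (is.atomic(metadata) && !is.null(names(metadata))) {
    grp <- as.character(metadata)
    names(grp) <- names(metadata)
  } else {
    metadata <- as.data.frame(metadata)
    if (!is.null(rownames(metadata)) &&
        !all(rownames(metadata) == as.character(seq_len(nrow(metadata))))) {
      ids <- rownames(metadata)
    } else {
      ids <- as.character(metadata[[1]])
      metadata <- metadata[, -1, drop = FALSE]
    }
    if (!group_key %in% names(metadata))
      stop(sprintf("metadata has no column '%s'", group_key))
    grp <- as.character(metadata[[group_key]])
    names(grp) <- ids
  }
  uncovered <- setdiff(sample_ids(table), names(grp))
  if (length(uncovered) > 0) {
    if (!drop_uncovered)
      stop(sprintf("metadata missing sample(s): %s",
                   paste(uncovered, collapse = ", ")))
    table <- subset_table(table, samples = setdiff(sample_ids(table),
                                                   uncovered))
  }
  count_table(table$counts, group = grp[sample_ids(table)])
}

#' Read a taxonomy table mapping feature IDs to a ranked lineage
#'
#' @param path TSV/CSV with feature IDs in the first column and one column
#'   per rank (e.g. kingdom...genus)
#' @param format `"tsv"` or `"csv"`
#' @return data.frame of rank labels, rownames = feature IDs
#' @export
read_taxonomy <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicated feature ID in taxonomy: '%s'",
                 ids[duplicated(ids)][1]))
  tax <- df[, -1, drop = FALSE]
  rownames(tax) <- ids
  tax
}

#' Write a count table, topic-abundance table or DA result to disk
#'
#' TSV/CSV with one header row and the sample (or feature) ID in the first
#' column. Real values are written with 15 significant digits so that
#' read-write round-trips preserve counts exactly and fractional values to
#' at least 12 significant digits.
#'
#' @param x a `count_table`, `topic_abundance`, `da_result`, matrix or
#'   data.frame
#' @param path destination
#' @param format `"tsv"` or `"csv"`
#' @export
write_table <- function(x, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  if (inherits(x, "count_table")) {
    m <- x$counts
    df <- data.frame(sample_id = rownames(m),
                     signif_digits(as.data.frame(m)),
                     check.names = FALSE)
  } else if (inherits(x, "topic_abundance")) {
    m <- x$values
    df <- data.frame(sample_id = rownames(m),
                     signif_digits(as.data.frame(m)),
                     check.names = FALSE)
  } else if (inherits(x, "da_result")) {
    df <- as.data.frame(x)
  } else if (is.matrix(x)) {
    df <- data.frame(id = rownames(x), signif_digits(as.data.frame(x)),
                     check.names = FALSE)
  } else {
    df <- as.data.frame(x)
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop(sprintf("cannot write '%s': %s", path,
                                      conditionMessage(e))))
  invisible(ok)
}

signif_digits <- function(df, digits = 15) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  df
}
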