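#' Run the full community-type workflow
#'
#' Orchestrates the whole analysis for one or two cohorts:
#' prevalence filtering (and optional genus aggregation), optional
#' topic-number selection, LDA per cohort, read-to-topic assignment,
#' cross-cohort topic matching by cosine similarity, differential
#' abundance of topics and of genera within significant matched topics,
#' and within-topic co-occurrence networks. Every intermediate table is
#' written as TSV under `out_dir`, together with a log and a summary of
#' validated community types with their top genera and direction of
#' change.
#'
#' @param config a named list or path to a YAML/JSON file with keys:
#'   \describe{
#'     \item{cohorts}{list of cohorts, each either
#'       `list(counts=, metadata=)` (file paths) or
#'       `list(table=)` (a `count_table` built in code)}
#'     \item{simulate}{alternative to `cohorts`: `"paired"` or
#'       `"single"` to generate synthetic cohorts}
#'     \item{group_key}{metadata column with the two-level label}
#'     \item{k}{topic number; or `k_grid` (e.g. `c(2, 20)` bounds) to
#'       select it}
#'     \item{seed, starts}{reproducibility and restarts}
#'     \item{filter_threshold}{prevalence cutoff, default `1e-5`}
#'     \item{cosine_threshold}{topic-match cutoff, default `0.80`}
#'     \item{p_max, q_max}{dual significance rule, defaults 0.05 / 0.25}
#'     \item{winsorize_genera}{winsorize the genus-level DA, default TRUE}
#'   }
#' @param out_dir run directory (created); default a temp directory
#' @return (invisibly) a list with the per-cohort models, topic tables,
#'   DA results, matches and the summary data.frame; all also on disk
#' @export
run_pipeline <- function(config, out_dir = tempfile("mtrun")) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    group_key = "group", seed = 1L, starts = 1L, filter_threshold = 1e-5,
    cosine_threshold = 0.80, p_max = 0.05, q_max = 0.25,
    winsorize_genera = TRUE, top_term_mass = 0.95, k = NULL,
    k_grid = NULL), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = logfile, append = TRUE)
    message(msg)
  }
  log_line("microtopics %s | R %s | seed %d",
           as.character(utils::packageVersion("microtopics")),
           getRversion(), cfg$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # ---- load or simulate cohorts -------------------------------------
  tables <- stage("load", {
    if (!is.null(cfg$simulate)) {
      beta <- generate_topics(K = cfg$sim_k %||% 10, V = cfg$sim_v %||% 160,
                              dominant_per_topic = cfg$sim_block %||% 8,
                              dominance = cfg$sim_dominance %||% 0.9)
      K <- nrow(beta)
      a_hc <- rep(cfg$sim_alpha %||% 1.5, K)
      a_ms <- a_hc
      a_ms[1] <- a_hc[1] * (cfg$sim_effect %||% 3)  # disease-enriched topic 1
      ab <- list(HC = a_hc, RRMS = a_ms)
      gs <- c(HC = cfg$sim_n %||% 25, RRMS = cfg$sim_n %||% 25)
      if (identical(cfg$simulate, "paired")) {
        pair <- generate_paired_cohorts(beta, epsilon = cfg$sim_epsilon %||% 0.01,
                                        alpha_by_group = ab,
                                        group_sizes = gs,
                                        vocab_overlap = cfg$sim_overlap %||% 0.95,
                                        seed = cfg$seed)
        list(cohort1 = pair$cohort_a$table, cohort2 = pair$cohort_b$table)
      } else {
        list(cohort1 = generate_cohort(beta, alpha_by_group = ab,
                                       group_sizes = gs,
                                       seed = cfg$seed)$table)
      }
    } else {
      out <- list()
      for (i in seq_along(cfg$cohorts)) {
        co <- cfg$cohorts[[i]]
        tab <- if (!is.null(co$table)) co$table else {
          t0 <- read_count_table(co$counts)
          md <- utils::read.table(co$metadata, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
          attach_metadata(t0, md, group_key = cfg$group_key)
        }
        out[[names(cfg$cohorts)[i] %||% paste0("cohort", i)]] <- tab
      }
      out
    }
  })
  log_line("loaded %d cohort(s): %s", length(tables),
           paste(sprintf("%s (%dx%d)", names(tables),
                         vapply(tables, function(t) nrow(t$counts), 0L),
                         vapply(tables, function(t) ncol(t$counts), 0L)),
                 collapse = ", "))

  # ---- preprocess ---------------------------------------------------
  tables <- stage("preprocess", lapply(tables, filter_low_prevalence,
                                       threshold = cfg$filter_threshold))
  for (nm in names(tables)) {
    write_table(tables[[nm]], file.path(out_dir,
                                        paste0(nm, "_filtered.tsv")))
    rem <- attr(tables[[nm]], "removed")
    utils::write.table(rem, file.path(out_dir, paste0(nm, "_removed.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("%s: %d features retained, %d removed at %g", nm,
             ncol(tables[[nm]]$counts), nrow(rem), cfg$filter_threshold)
  }

  # ---- choose K -----------------------------------------------------
  K <- cfg$k
  if (is.null(K)) {
    ks <- stage("choose-k", select_topic_number(
      unname(tables), k_grid = seq(cfg$k_grid[1], cfg$k_grid[2]),
      seed = cfg$seed, n_starts = cfg$starts))
    for (ti in seq_along(ks$metrics))
      write_table(ks$metrics[[ti]],
                  file.path(out_dir, sprintf("kselection_cohort%d.tsv", ti)))
    K <- ks$chosen_k
    log_line("selected K = %d (per-metric argmins: %s)", K,
             paste(unlist(ks$best_k_per_metric), collapse = ", "))
  }

  # ---- fit, assign --------------------------------------------------
  models <- topic_tables <- list()
  for (nm in names(tables)) {
    models[[nm]] <- stage("fit", fit_lda(tables[[nm]], K = K,
                                         seed = cfg$seed,
                                         n_starts = cfg$starts))
    write_table(models[[nm]]$beta,
                file.path(out_dir, paste0(nm, "_beta.tsv")))
    write_table(models[[nm]]$gamma_norm,
                file.path(out_dir, paste0(nm, "_gamma.tsv")))
    topic_tables[[nm]] <- stage("assign",
                                assign_reads(models[[nm]], tables[[nm]]))
    write_table(topic_tables[[nm]],
                file.path(out_dir, paste0(nm, "_topic_abundance.tsv")))
    log_line("%s: fitted K = %d (%s), reads assigned", nm, K,
             if (models[[nm]]$converged) "converged" else "max_iter")
  }

  # ---- match topics across cohorts ----------------------------------
  matches <- NULL
  if (length(tables) >= 2) {
    cm <- stage("match", topic_cosine_matrix(models[[1]]$beta,
                                             models[[2]]$beta))
    write_table(cm, file.path(out_dir, "cosine_matrix.tsv"))
    matches <- match_topics(cm, threshold = cfg$cosine_threshold)
    write_table(matches, file.path(out_dir, "topic_matches.tsv"))
    log_line("matching: %d pair(s) at cosine >= %.2f", nrow(matches),
             cfg$cosine_threshold)
  } else {
    log_line("single cohort: matching stage skipped")
  }

  # ---- differential abundance of topics -----------------------------
  da_topics <- list()
  for (nm in names(tables)) {
    da_topics[[nm]] <- stage("da-topics",
                             linda_fit(topic_tables[[nm]],
                                       winsorize = FALSE,
                                       p_max = cfg$p_max, q_max = cfg$q_max))
    write_table(da_topics[[nm]],
                file.path(out_dir, paste0(nm, "_da_topics.tsv")))
    log_line("%s: %d/%d topics differentially abundant", nm,
             sum(da_topics[[nm]]$significant), K)
  }

  # ---- validated community types + genus-level DA within them -------
  summary_df <- data.frame()
  da_genera <- list()
  networks <- list()
  if (!is.null(matches) && nrow(matches) > 0) {
    sig1 <- da_topics[[1]]$feature[da_topics[[1]]$significant]
    sig2 <- da_topics[[2]]$feature[da_topics[[2]]$significant]
    validated <- matches[matches$topic_a %in% sig1 &
                           matches$topic_b %in% sig2, , drop = FALSE]
    for (i in seq_len(nrow(validated))) {
      ta <- validated$topic_a[i]; tb <- validated$topic_b[i]
      eff_a <- da_topics[[1]]$effect_log2[da_topics[[1]]$feature == ta]
      eff_b <- da_topics[[2]]$effect_log2[da_topics[[2]]$feature == tb]
      genera_a <- top_terms(models[[1]], ta,
                            cutoff = cfg$top_term_mass)$genus
      key <- sprintf("%s|%s", ta, tb)
      genera_present <- intersect(genera_a, feature_ids(tables[[1]]))
      da_genera[[key]] <- stage("da-genera", linda_fit(
        subset_table(tables[[1]], features = genera_present),
        winsorize = cfg$winsorize_genera,
        p_max = cfg$p_max, q_max = cfg$q_max))
      write_table(da_genera[[key]], file.path(out_dir,
        sprintf("da_genera_%s_%s.tsv", ta, tb)))
      networks[[key]] <- stage("network", topic_network(
        tables[[1]], genera_present))
      write_edge_list(networks[[key]], file.path(out_dir,
        sprintf("network_%s_%s.tsv", ta, tb)))
      summary_df <- rbind(summary_df, data.frame(
        topic_a = ta, topic_b = tb, cosine = validated$cosine[i],
        effect_a = eff_a, effect_b = eff_b,
        direction_a = ifelse(eff_a > 0, "up", "down"),
        direction_b = ifelse(eff_b > 0, "up", "down"),
        concordant = sign(eff_a) == sign(eff_b),
        n_top_genera = length(genera_a),
        n_sig_genera = sum(da_genera[[key]]$significant),
        stringsAsFactors = FALSE))
    }
    log_line("validated community types: %d (%d concordant)",
             nrow(summary_df), sum(summary_df$concordant))
  }
  utils::write.table(summary_df, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(tables = tables, models = models,
                 topic_tables = topic_tables, matches = matches,
                 da_topics = da_topics, da_genera = da_genera,
                 networks = networks, summary = summary_df,
                 out_dir = out_dir, k = K))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
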