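#' Run the full SWB pipeline and write all report tables
#'
#' One call that regenerates every report from either a synthetic corpus
#' (pass a [swb_sim_config()]) or on-disk inputs (pass file paths): it fits
#' the SWL model ([swb_fit()]), then writes
#' \itemize{
#'   \item `affect_correlations.csv` — affect/SWL correlation matrix;
#'   \item `swl_evaluation.csv` — the feature-set ladder (r, p, RMSE per set
#'     plus baseline);
#'   \item `selected_features.csv` — elastic-net selection with coefficients;
#'   \item `cesd_validity.csv` — CES-D predictive-validity table (when CES-D
#'     scores are available);
#'   \item `activity_sentiment.csv` — activity z-scores;
#'   \item `swb_profile.csv` — per-user predicted SWL and sentiment features;
#'   \item `manifest.json` — seeds, parameters and artifact list, sufficient
#'     to reproduce the run.
#' }
#'
#' @param out_dir output directory (created if needed).
#' @param sim_config a [swb_sim_config()] for synthetic mode, or `NULL`.
#' @param corpus_path,outcomes_path,lexicon_path,topic_table_path,
#'   category_lexicon_path,activity_lexicon_path input files for real-corpus
#'   mode (ignored in synthetic mode; `activity_lexicon_path` may be `NULL`
#'   to use the built-in synthetic activity lexicon).
#' @param seed master seed for the modelling stages.
#' @param ... further arguments passed to [swb_fit()] (e.g. `grid`,
#'   `mixing`, `ntree`).
#' @return invisibly, a list with the fitted model and all report tables.
#' @export
swb_run <- function(out_dir, sim_config = NULL,
                    corpus_path = NULL, outcomes_path = NULL,
                    lexicon_path = NULL, topic_table_path = NULL,
                    category_lexicon_path = NULL,
                    activity_lexicon_path = NULL,
                    seed = 1, ...) {
  if (is.null(sim_config) == is.null(corpus_path))
    .fail("provide exactly one of sim_config (synthetic mode) or corpus_path (file mode)")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    .fail("cannot create output directory: %s", out_dir)
  log_line <- function(...) message(sprintf(...))

  if (!is.null(sim_config)) {
    log_line("stage corpus: generating synthetic corpus (seed %d)",
             sim_config$seed)
    sim <- sim_corpus(sim_config)
    corpus <- sim$corpus
    outcomes <- data.frame(user_id = sim$truth$user_id,
                           swl = sim$truth$swl_self, cesd = sim$truth$cesd)
    lexicon <- sim$lexicon; ttab <- sim$topic_table
    cats <- sim$category_lexicon; acts <- sim$activity_lexicon
    mode <- "synthetic"
  } else {
    log_line("stage corpus: reading %s", corpus_path)
    corpus <- read_corpus(corpus_path)
    outcomes <- read_outcomes(outcomes_path)
    lexicon <- read_valence_lexicon(lexicon_path)
    ttab <- read_topic_table(topic_table_path)
    cats <- read_category_lexicon(category_lexicon_path)
    acts <- if (is.null(activity_lexicon_path)) sim_activity_lexicon()
            else read_activity_lexicon(activity_lexicon_path)
    mode <- "files"
  }

  log_line("stage preprocess: %d statuses from %d users", nrow(corpus),
           length(unique(corpus$user_id)))
  if (!"tokens" %in% names(corpus)) corpus <- preprocess_corpus(corpus)

  log_line("stage fit: elastic-net selection + random forest")
  fit <- swb_fit(corpus, outcomes, lexicon, ttab, cats, seed = seed, ...)

  corr <- affect_swl_correlations(fit$affect, outcomes)
  corr_df <- data.frame(variable = rownames(corr$r), round(corr$r, 4))
  prof <- swb_profile(fit)

  validity <- NULL
  if (any(is.finite(outcomes$cesd))) {
    log_line("stage validity: %d users with CES-D",
             sum(is.finite(outcomes$cesd)))
    validity <- tryCatch(cesd_validity(fit, outcomes),
                         error = function(e) {
                           log_line("stage validity skipped: %s",
                                    conditionMessage(e)); NULL
                         })
  }

  log_line("stage activity: scoring activity sentiment")
  act <- activity_sentiment(corpus, acts, lexicon)

  paths <- c(affect = "affect_correlations.csv",
             evaluation = "swl_evaluation.csv",
             selection = "selected_features.csv",
             validity = "cesd_validity.csv",
             activity = "activity_sentiment.csv",
             profile = "swb_profile.csv")
  paths <- file.path(out_dir, paths)
  names(paths) <- c("affect", "evaluation", "selection", "validity",
                    "activity", "profile")
  utils::write.csv(corr_df, paths["affect"], row.names = FALSE)
  utils::write.csv(fit$evaluation, paths["evaluation"], row.names = FALSE)
  utils::write.csv(as.data.frame(fit$selection), paths["selection"],
                   row.names = FALSE)
  if (!is.null(validity))
    utils::write.csv(as.data.frame(validity), paths["validity"],
                     row.names = FALSE)
  utils::write.csv(act, paths["activity"], row.names = FALSE)
  utils::write.csv(prof, paths["profile"], row.names = FALSE)

  manifest <- list(
    package = "swbprofiler",
    version = as.character(utils::packageVersion("swbprofiler")),
    mode = mode, seed = seed,
    sim_config = if (!is.null(sim_config)) unclass(sim_config),
    fit_config = fit$config,
    artifacts = as.list(basename(paths[file.exists(paths)])))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line("done: reports in %s", out_dir)
  invisible(list(fit = fit, affect_correlations = corr,
                 validity = validity, activity = act, profile = prof,
                 manifest = manifest))
}
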