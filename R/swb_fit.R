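#' Fit the satisfaction-with-life model from a status corpus
#'
#' The end-to-end fitting pipeline: preprocess the corpus (emoticon
#' conversion, hyperlink/digit/punctuation removal), apply the minimum-status
#' retention filter, compute affect, category and topic features, split users
#' into train/test partitions, reduce the category/topic space with an
#' elastic net fitted on the training partition, then fit random-forest
#' regressions of self-reported SWL on nested feature sets and evaluate each
#' on the held-out test users (Pearson r, two-sided p, RMSE) against a
#' jittered-median baseline. Finally a forest on the full feature set is
#' refitted on *all* users to yield out-of-bag machine-predicted SWL for
#' every user — the SWL constituent of the SWB profile used in
#' [cesd_validity()].
#'
#' The three sentiment features (mean sentiment, positive frequency, negative
#' frequency) bypass selection and always enter the models that include
#' sentiment; selection operates on category and topic columns only.
#'
#' @param corpus data frame `user_id`, `text` (raw) or `user_id`, `tokens`
#'   (already preprocessed).
#' @param outcomes data frame `user_id`, `swl` (self-reported, 1--7 scale).
#' @param lexicon valence lexicon (`word`, `valence`).
#' @param topic_table truncated topic table (`topic_id`, `word`, `p_tw`).
#' @param category_lexicon category lexicon (`category`, `word`).
#' @param smileys smiley map for preprocessing.
#' @param min_statuses retention threshold (default 30).
#' @param train_fraction training fraction of users (default 1873/2612).
#' @param mixing elastic-net mixing parameter (default 0.1).
#' @param ntree,mtry forest hyperparameters used when `grid` is `NULL`
#'   (defaults 1000 and 3).
#' @param grid optional data frame (`ntree`, `mtry`) or `"default"` for the
#'   eight-cell grid; when given, a manual search on the full feature set
#'   picks the cell with the best out-of-bag correlation, and that cell is
#'   used for every feature-set model.
#' @param seed master seed; preprocessing is deterministic, and the split,
#'   selection folds, forests and baseline jitter all derive stage seeds
#'   from it.
#' @return an object of class `swb_fit`; see Details.
#' @details The returned object has components `evaluation` (the feature-set
#'   ladder: one row per feature set with `feature_set`, `n_features`, `r`,
#'   `p`, `rmse`), `selection` (the elastic-net result), `oob_swl`
#'   (machine-predicted SWL for all users, named), `affect` (per-user affect
#'   features), `features` (the full feature matrix), `split`, `forest` (the
#'   full-set forest fitted on train), `forest_all` (fitted on all users),
#'   `config` (hyperparameters actually used) and `y` (named self-reported
#'   SWL). Methods: [print.swb_fit()], [summary.swb_fit()], `coef`,
#'   `predict`, `fitted` (OOB predictions), `residuals`, `plot`.
#' @seealso [swb_profile()], [cesd_validity()], [activity_sentiment()]
#' @export
swb_fit <- function(corpus, outcomes, lexicon, topic_table, category_lexicon,
                    smileys = default_smiley_map(), min_statuses = 30,
                    train_fraction = 1873 / 2612, mixing = 0.1,
                    ntree = 1000, mtry = 3, grid = NULL, seed = 1) {
  cl <- match.call()
  .check_cols(outcomes, c("user_id", "swl"), "outcomes")

  if (!"tokens" %in% names(corpus))
    corpus <- preprocess_corpus(corpus, smileys)
  corpus <- filter_min_statuses(corpus, min_statuses)

  fm <- build_feature_matrix(corpus, lexicon, topic_table, category_lexicon)
  al <- .align_users(fm$X, outcomes)
  X <- al$X; y <- stats::setNames(al$y, al$ids)
  if (length(y) < 20L) .fail("only %d users with outcomes; too few to model",
                             length(y))

  split <- split_train_test(al$ids, train_fraction, seed = seed)
  tr <- split$train; te <- split$test

  sent_cols <- paste0("affect:", c("mean_sentiment", "pos_freq", "neg_freq"))
  cand_cols <- setdiff(colnames(X), paste0("affect:",
    c("mean_sentiment", "pos_freq", "neg_freq", "pos_neg_ratio")))
  selection <- elastic_net_select(X[tr, cand_cols, drop = FALSE], y[tr],
                                  mixing = mixing, seed = seed)
  sel_cat <- grep("^cat:", selection$feature, value = TRUE)
  sel_topic <- grep("^topic:", selection$feature, value = TRUE)

  sets <- list(
    "selected categories" = sel_cat,
    "selected topics" = sel_topic,
    "selected topics + sentiment" = c(sel_topic, sent_cols),
    "selected topics + categories + sentiment" =
      c(sel_topic, sel_cat, sent_cols)
  )
  sets <- sets[lengths(sets) > 0]
  full_cols <- unique(c(sel_topic, sel_cat, sent_cols))

  if (identical(grid, "default")) grid <- default_forest_grid()
  if (!is.null(grid)) {
    gs <- grid_search(X[tr, full_cols, drop = FALSE], y[tr], grid = grid,
                      seed = seed)
    ntree <- gs$best$ntree
    mtry <- gs$best$mtry
    grid_results <- gs$results
  } else grid_results <- NULL

  evaluation <- data.frame(feature_set = "baseline", n_features = 1L,
                           evaluate_predictions(
                             baseline_predict(y[tr], length(te), seed = seed),
                             y[te]))
  forests <- list()
  for (nm in names(sets)) {
    cols <- sets[[nm]]
    f <- fit_forest(X[tr, cols, drop = FALSE], y[tr], ntree = ntree,
                    mtry = mtry, seed = seed)
    forests[[nm]] <- f
    evaluation <- rbind(evaluation,
      data.frame(feature_set = nm, n_features = length(cols),
                 evaluate_predictions(.forest_predict(f, X[te, , drop = FALSE]),
                                      y[te])))
  }
  rownames(evaluation) <- NULL

  # refit the full model on every user; its OOB predictions are the
  # machine-predicted SWL entering the SWB profile
  forest_all <- fit_forest(X[, full_cols, drop = FALSE], y, ntree = ntree,
                           mtry = mtry, seed = stage_seed(seed, 5))
  oob_swl <- stats::setNames(forest_all$oob, al$ids)

  structure(list(call = cl, evaluation = evaluation, selection = selection,
                 oob_swl = oob_swl, affect = fm$affect, features = X,
                 split = split, forest = forests[[length(forests)]],
                 forests = forests, forest_all = forest_all,
                 y = y, grid_results = grid_results,
                 config = list(min_statuses = min_statuses,
                               train_fraction = train_fraction,
                               mixing = mixing, ntree = ntree, mtry = mtry,
                               seed = seed)),
            class = "swb_fit")
}

#' @export
print.swb_fit <- function(x, ...) {
  cat("Satisfaction-with-life model (elastic-net selection + random forest)\n")
  cat(sprintf("  users: %d (%d train / %d test); seed %d\n",
              length(x$y), length(x$split$train), length(x$split$test),
              x$config$seed))
  cat(sprintf("  selected features: %d of %d candidates (mixing %.2g)\n",
              nrow(x$selection), attr(x$selection, "n_candidates"),
              x$config$mixing))
  cat(sprintf("  forest: ntree = %d, mtry = %d\n", x$config$ntree,
              x$config$mtry))
  full <- x$evaluation[nrow(x$evaluation), ]
  cat(sprintf("  test-set r = %.3f (p = %.3g), RMSE = %.3f [%s]\n",
              full$r, full$p, full$rmse, full$feature_set))
  invisible(x)
}

#' Summarize a fitted SWL model
#'
#' @param object an `swb_fit`.
#' @param ... unused.
#' @return the object, invisibly, after printing the feature-set ladder and
#'   selection summary.
#' @export
summary.swb_fit <- function(object, ...) {
  print(object)
  cat("\nFeature-set ladder (held-out test users):\n")
  ev <- object$evaluation
  ev$r <- round(ev$r, 3); ev$p <- signif(ev$p, 3); ev$rmse <- round(ev$rmse, 3)
  print.data.frame(ev, row.names = FALSE)
  cat("\nTop selected features:\n")
  print.data.frame(utils::head(object$selection, 10), row.names = FALSE)
  invisible(object)
}

#' @export
coef.swb_fit <- function(object, ...) {
  stats::setNames(object$selection$coefficient, object$selection$feature)
}

#' Predict SWL for new users
#'
#' @param object an `swb_fit`.
#' @param newdata a corpus data frame (`user_id`, `text` or `tokens`), or a
#'   ready feature matrix with named columns. Omitted: returns OOB
#'   predictions for the fitted users.
#' @param lexicon,topic_table,category_lexicon resources, required when
#'   `newdata` is a corpus (they are not stored in the fit; pass the same
#'   resources used at fit time).
#' @param model which forest to predict with: `"all"` (default; fitted on
#'   every user — use its OOB predictions, not in-bag ones, for fitted
#'   users) or `"train"` (fitted on the training partition only — the right
#'   choice for honest predictions on the held-out test users).
#' @param ... unused.
#' @return named numeric vector of predicted SWL; forest averaging keeps
#'   predictions inside the training response range.
#' @export
predict.swb_fit <- function(object, newdata = NULL, lexicon = NULL,
                            topic_table = NULL, category_lexicon = NULL,
                            model = c("all", "train"), ...) {
  model <- match.arg(model)
  if (is.null(newdata)) return(object$oob_swl)
  if (is.data.frame(newdata)) {
    if (is.null(lexicon) || is.null(topic_table) || is.null(category_lexicon))
      .fail("predicting from a corpus needs lexicon, topic_table and category_lexicon")
    if (!"tokens" %in% names(newdata))
      newdata <- preprocess_corpus(newdata)
    newdata <- build_feature_matrix(newdata, lexicon, topic_table,
                                    category_lexicon)$X
  }
  forest <- if (model == "train") object$forest else object$forest_all
  stats::setNames(.forest_predict(forest, newdata), rownames(newdata))
}

#' @export
fitted.swb_fit <- function(object, ...) object$oob_swl

#' @export
residuals.swb_fit <- function(object, ...) object$y - object$oob_swl

#' Diagnostic plots for a fitted SWL model
#'
#' `type = "prediction"` draws held-out machine-predicted against
#' self-reported SWL for the test users; `type = "importance"` draws the top
#' permutation importances of the full model, computed on the test partition.
#'
#' @param x an `swb_fit`.
#' @param type `"prediction"` or `"importance"`.
#' @param top_n features shown by the importance plot.
#' @param ... passed to the underlying plotting function.
#' @export
plot.swb_fit <- function(x, type = c("prediction", "importance"),
                         top_n = 15, ...) {
  type <- match.arg(type)
  te <- x$split$test
  if (type == "prediction") {
    pred <- .forest_predict(x$forest, x$features[te, , drop = FALSE])
    graphics::plot(x$y[te], pred, xlab = "self-reported SWL",
                   ylab = "machine-predicted SWL",
                   main = "Held-out SWL prediction", ...)
    graphics::abline(0, 1, lty = 2)
  } else {
    imp <- variable_importance(x$forest, x$features[te, , drop = FALSE],
                               x$y[te], seed = x$config$seed)
    imp <- utils::head(imp, top_n)
    op <- graphics::par(mar = c(4, 10, 2, 1)); on.exit(graphics::par(op))
    graphics::barplot(rev(imp$importance), names.arg = rev(imp$feature),
                      horiz = TRUE, las = 1,
                      xlab = "permutation importance (increase in MSE)",
                      main = "Variable importance", ...)
  }
  invisible(x)
}
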