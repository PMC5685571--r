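#' Assemble the subjective well-being profile
#'
#' Bundles each user's machine-predicted SWL (the out-of-bag prediction from
#' the all-user forest) with the three sentiment features into the four-field
#' SWB profile.
#'
#' @param fit an [swb_fit] object (supplies OOB SWL and affect), or a named
#'   numeric vector of OOB SWL if `affect` is given separately.
#' @param affect per-user affect data frame; defaults to the one inside `fit`.
#' @return data frame with columns `user_id`, `predicted_swl`,
#'   `mean_sentiment`, `pos_freq`, `neg_freq`.
#' @export
swb_profile <- function(fit, affect = NULL) {
  if (inherits(fit, "swb_fit")) {
    oob <- fit$oob_swl
    if (is.null(affect)) affect <- fit$affect
  } else oob <- fit
  .check_cols(affect, c("user_id", "mean_sentiment", "pos_freq", "neg_freq"),
              "affect features")
  miss <- setdiff(affect$user_id, names(oob))
  # users outside the modelled set simply drop out; a modelled user without
  # an OOB prediction is an error
  affect <- affect[affect$user_id %in% names(oob), , drop = FALSE]
  if (anyNA(oob[affect$user_id]))
    .fail("missing OOB prediction for user(s): %s",
          paste(utils::head(affect$user_id[is.na(oob[affect$user_id])], 5),
                collapse = ", "))
  data.frame(user_id = affect$user_id,
             predicted_swl = unname(oob[affect$user_id]),
             mean_sentiment = affect$mean_sentiment,
             pos_freq = affect$pos_freq,
             neg_freq = affect$neg_freq,
             stringsAsFactors = FALSE)
}

#' Correlations of profile fields with CES-D
#'
#' Pearson correlation (and two-sided p) of each SWB-profile field with the
#' CES-D depression score, over users having a CES-D value. With a working
#' pipeline the SWL fields correlate negatively with depression symptoms.
#'
#' @param profile data frame from [swb_profile()].
#' @param outcomes data frame with `user_id` and `cesd`.
#' @return data frame `field`, `r`, `p`, `n`.
#' @export
criterion_correlations <- function(profile, outcomes) {
  .check_cols(outcomes, c("user_id", "cesd"), "outcomes")
  m <- merge(profile, outcomes[, c("user_id", "cesd")], by = "user_id")
  m <- m[is.finite(m$cesd), , drop = FALSE]
  if (nrow(m) < 3L) .fail("fewer than 3 users with CES-D scores")
  fields <- setdiff(names(profile), "user_id")
  out <- do.call(rbind, lapply(fields, function(f) {
    ct <- suppressWarnings(.cor_test(m[[f]], m$cesd))
    data.frame(field = f, r = ct$r, p = ct$p, n = ct$n)
  }))
  rownames(out) <- NULL
  out
}

#' Predictive validity of the SWB profile against CES-D
#'
#' Quantifies how much information each profile variant carries about
#' depression symptoms: users with a CES-D score are split 70/30, and a
#' random forest predicts CES-D from each of three feature sets — sentiment
#' only (3 features), self-reported SWL + sentiment (4), machine-predicted
#' SWL + sentiment (4, the SWB profile) — plus the jittered-median baseline.
#' All four rows share the identical split and seed; forest hyperparameters
#' default to the ones of the SWL fit.
#'
#' @param fit an [swb_fit] object.
#' @param outcomes data frame `user_id`, `swl`, `cesd` (`cesd` may be `NA`
#'   for users lacking the scale; they are excluded).
#' @param train_fraction CES-D training fraction (default 0.7).
#' @param ntree,mtry forest hyperparameters (default: those of `fit`).
#' @param min_users smallest usable CES-D subsample (default 20).
#' @param seed seed (default: the fit's).
#' @return object of class `swb_validity`: data frame `feature_set`,
#'   `n_features`, `r`, `p`, `rmse`, `n`, with the split sizes as attributes.
#' @export
cesd_validity <- function(fit, outcomes, train_fraction = 0.7,
                          ntree = NULL, mtry = NULL, min_users = 20,
                          seed = NULL) {
  stopifnot(inherits(fit, "swb_fit"))
  .check_cols(outcomes, c("user_id", "swl", "cesd"), "outcomes")
  if (is.null(ntree)) ntree <- fit$config$ntree
  if (is.null(mtry)) mtry <- fit$config$mtry
  if (is.null(seed)) seed <- fit$config$seed

  prof <- swb_profile(fit)
  m <- merge(prof, outcomes, by = "user_id")
  m <- m[is.finite(m$cesd), , drop = FALSE]
  if (nrow(m) < min_users)
    .fail("only %d users with CES-D; need at least %d", nrow(m), min_users)

  split <- split_train_test(m$user_id, train_fraction, seed = stage_seed(seed, 41))
  tr <- match(split$train, m$user_id)
  te <- match(split$test, m$user_id)

  sent <- c("mean_sentiment", "pos_freq", "neg_freq")
  sets <- list("sentiment" = sent,
               "self-reported SWL + sentiment" = c("swl", sent),
               "machine-predicted SWL + sentiment" = c("predicted_swl", sent))

  out <- data.frame(feature_set = "baseline", n_features = 1L,
                    evaluate_predictions(
                      baseline_predict(m$cesd[tr], length(te),
                                       seed = stage_seed(seed, 42)),
                      m$cesd[te]))
  for (nm in names(sets)) {
    Xc <- as.matrix(m[, sets[[nm]], drop = FALSE])
    rownames(Xc) <- m$user_id
    f <- fit_forest(Xc[tr, , drop = FALSE], m$cesd[tr], ntree = ntree,
                    mtry = min(mtry, length(sets[[nm]])), seed = seed)
    pred <- .forest_predict(f, Xc[te, , drop = FALSE])
    out <- rbind(out, data.frame(feature_set = nm,
                                 n_features = length(sets[[nm]]),
                                 evaluate_predictions(pred, m$cesd[te])))
  }
  rownames(out) <- NULL
  attr(out, "n_train") <- length(tr)
  attr(out, "n_test") <- length(te)
  attr(out, "seed") <- seed
  class(out) <- c("swb_validity", "data.frame")
  out
}

#' @export
print.swb_validity <- function(x, ...) {
  cat(sprintf("CES-D predictive validity (%d train / %d test users)\n",
              attr(x, "n_train"), attr(x, "n_test")))
  y <- x
  y$r <- round(y$r, 3); y$p <- signif(y$p, 3); y$rmse <- round(y$rmse, 2)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
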