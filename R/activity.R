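#' Match statuses to activity word lists
#'
#' A status matches an activity iff it contains at least one of the
#' activity's terms; a status may match several activities. Matching is
#' token-exact on preprocessed text; a multi-word term ("ice cream") matches
#' as a bigram of consecutive tokens.
#'
#' @param pcorpus preprocessed corpus (columns `user_id`, `tokens`; a
#'   `status_id` column is used when present, otherwise row numbers).
#' @param activity_lexicon data frame (`activity`, `word`).
#' @return named list: for each activity, the integer row indices of matching
#'   statuses in `pcorpus`.
#' @export
match_activity_statuses <- function(pcorpus, activity_lexicon) {
  .check_cols(pcorpus, "tokens", "preprocessed corpus")
  .check_cols(activity_lexicon, c("activity", "word"), "activity lexicon")
  toks <- pcorpus$tokens
  # bigram stream per status for multi-word terms
  has_bigram <- any(grepl(" ", activity_lexicon$word, fixed = TRUE))
  bigrams <- if (has_bigram) {
    lapply(toks, function(tk) {
      if (length(tk) < 2L) character(0)
      else paste(tk[-length(tk)], tk[-1L])
    })
  } else NULL
  acts <- split(activity_lexicon$word, activity_lexicon$activity)
  out <- lapply(acts, function(words) {
    uni <- words[!grepl(" ", words, fixed = TRUE)]
    bi <- setdiff(words, uni)
    hit <- vapply(toks, function(tk) any(tk %in% uni), logical(1))
    if (length(bi) && has_bigram)
      hit <- hit | vapply(bigrams, function(bg) any(bg %in% bi), logical(1))
    which(hit)
  })
  out[sort(names(out))]
}

#' Activity sentiment z-scores
#'
#' For each activity, the mean per-status sentiment of its matching statuses
#' is standardized across activities: z = (activity mean - grand mean over
#' activities) / SD over activities, with the population-SD convention, so
#' the reported z-scores have mean 0 and SD 1 by construction (all zero in
#' the degenerate equal-means case). The mean per
#' matched status (not the raw sum, which scales with corpus size) is the
#' standardized quantity; the raw sum is reported alongside.
#'
#' @param matches activity-to-status-index list from
#'   [match_activity_statuses()].
#' @param scores per-status scores from [score_status()] on the same corpus
#'   (its `valence_sum` column, aligned with corpus rows).
#' @return data frame `activity`, `n_statuses`, `sentiment_sum`,
#'   `mean_sentiment`, `z_score`, sorted by descending z.
#' @export
activity_z_scores <- function(matches, scores) {
  v <- if (is.data.frame(scores)) scores$valence_sum else scores
  nonempty <- names(matches)[lengths(matches) > 0]
  if (length(nonempty) < 2L)
    .fail("need at least 2 activities with matched statuses (got %d)",
          length(nonempty))
  means <- vapply(matches[nonempty], function(i) mean(v[i]), numeric(1))
  sums <- vapply(matches[nonempty], function(i) sum(v[i]), numeric(1))
  sd_pop <- sqrt(mean((means - mean(means))^2))
  # all activities at the grand mean: every z is 0 by symmetry
  z <- if (sd_pop == 0) rep(0, length(means)) else (means - mean(means)) / sd_pop
  out <- data.frame(activity = nonempty,
                    n_statuses = lengths(matches[nonempty]),
                    sentiment_sum = unname(sums),
                    mean_sentiment = unname(means),
                    z_score = unname(z),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$z_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Activity-conditioned sentiment in one call
#'
#' Convenience wrapper: scores every status with the valence lexicon, matches
#' statuses to activities, and standardizes the per-activity mean sentiment
#' into z-scores.
#'
#' @param pcorpus preprocessed corpus.
#' @param activity_lexicon activity lexicon (`activity`, `word`).
#' @param lexicon valence lexicon.
#' @return the data frame of [activity_z_scores()].
#' @export
activity_sentiment <- function(pcorpus, activity_lexicon, lexicon) {
  scores <- score_status(pcorpus$tokens, lexicon)
  matches <- match_activity_statuses(pcorpus, activity_lexicon)
  activity_z_scores(matches, scores)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement between two categorical rating vectors:
#' kappa = (p_o - p_e) / (1 - p_e), where p_o is the observed agreement
#' fraction and p_e the expected agreement from the two raters' marginal
#' label distributions. The two-sided p-value tests kappa = 0 via the
#' large-sample normal approximation of kappa's standard error under
#' independence.
#'
#' @param ratings_a,ratings_b equal-length label vectors (length >= 2).
#' @return list: `kappa`, `p_value`, `se0` (null SE), `p_o`, `p_e`, `n`.
#'   Both raters constant and identical (p_e = 1) makes kappa undefined
#'   (`NA`, with a warning).
#' @export
#' @examples
#' cohens_kappa(c("x", "x", "y", "y"), c("x", "x", "y", "x"))
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b))
    .fail("rating vectors differ in length")
  n <- length(ratings_a)
  if (n < 2L) .fail("need at least 2 rated items")
  lev <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(as.character(ratings_a), levels = lev)
  b <- factor(as.character(ratings_b), levels = lev)
  tab <- table(a, b) / n
  p_o <- sum(diag(tab))
  pa <- rowSums(tab); pb <- colSums(tab)
  p_e <- sum(pa * pb)
  if (p_e >= 1) {
    warning("both raters constant and identical; kappa undefined")
    return(list(kappa = NA_real_, p_value = NA_real_, se0 = NA_real_,
                p_o = p_o, p_e = p_e, n = n))
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  # null SE (Fleiss/Cohen large-sample form under rater independence)
  se0 <- sqrt((p_e + p_e^2 - sum(pa * pb * (pa + pb))) / (n * (1 - p_e)^2))
  z <- kappa / se0
  list(kappa = kappa, p_value = 2 * stats::pnorm(-abs(z)), se0 = se0,
       p_o = p_o, p_e = p_e, n = n)
}
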