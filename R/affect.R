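#' Score statuses by valence word counting
#'
#' Polarity detection by lexicon lookup: each token found in the positive set
#' adds +1 to the status valence sum, each token in the negative set adds -1;
#' repeated valence words each count (words are counted, not types). Polarity
#' is the sign of the sum, with zero mapped to neutral. Per-status scores are
#' deliberately not length-normalized; only user-level aggregation divides by
#' the status count (see [user_affect()]).
#'
#' @param tokens a character vector of tokens (one status), or a list of such
#'   vectors (many statuses).
#' @param lexicon valence lexicon (`word`, `valence`).
#' @return data frame with one row per status: `valence_sum` (integer) and
#'   `polarity` (`"positive"`, `"negative"` or `"neutral"`).
#' @export
#' @examples
#' lex <- data.frame(word = c("love", "rain", "bad"), valence = c(1, 1, -1))
#' score_status(c("love", "bad", "bad"), lex)
score_status <- function(tokens, lexicon) {
  .check_cols(lexicon, c("word", "valence"), "valence lexicon")
  if (!is.list(tokens)) tokens <- list(tokens)
  n <- length(tokens)
  flat <- unlist(tokens, use.names = FALSE)
  idx <- rep.int(seq_len(n), lengths(tokens))
  val <- lexicon$valence[match(flat, lexicon$word)]
  hit <- !is.na(val)
  sums <- integer(n)
  if (any(hit)) {
    agg <- rowsum(val[hit], idx[hit])
    sums[as.integer(rownames(agg))] <- as.integer(agg[, 1])
  }
  data.frame(
    valence_sum = sums,
    polarity = c("negative", "neutral", "positive")[sign(sums) + 2L],
    stringsAsFactors = FALSE
  )
}

#' User-level affect features
#'
#' Aggregates per-status valence sums into the four affect variables:
#' \describe{
#'   \item{mean_sentiment}{affect intensity — the sum of all valence-word
#'     contributions divided by the number of status updates (status counts,
#'     not word counts, normalize user output, because status lengths are
#'     highly uneven).}
#'   \item{pos_freq, neg_freq}{affect frequency — the proportions of positive
#'     and negative statuses among all of the user's statuses (neutral
#'     statuses stay in the denominator).}
#'   \item{pos_neg_ratio}{positive-to-negative status ratio, add-one smoothed
#'     as (#pos + 1)/(#neg + 1) because a raw ratio is undefined for the many
#'     users with no negative status; the raw ratio is also returned
#'     (`pos_neg_ratio_raw`, `NA` when #neg = 0).}
#' }
#'
#' @param scores data frame from [score_status()] (one user), or its
#'   `valence_sum` column.
#' @return one-row data frame with `n_statuses`, `mean_sentiment`, `pos_freq`,
#'   `neg_freq`, `pos_neg_ratio`, `pos_neg_ratio_raw`.
#' @export
#' @examples
#' user_affect(data.frame(valence_sum = c(2, -1, 0)))
user_affect <- function(scores) {
  v <- if (is.data.frame(scores)) scores$valence_sum else scores
  n <- length(v)
  if (n < 1L) .fail("user has zero statuses; should have been filtered out")
  npos <- sum(v > 0); nneg <- sum(v < 0)
  data.frame(
    n_statuses = n,
    mean_sentiment = sum(v) / n,
    pos_freq = npos / n,
    neg_freq = nneg / n,
    pos_neg_ratio = (npos + 1) / (nneg + 1),
    pos_neg_ratio_raw = if (nneg > 0) npos / nneg else NA_real_
  )
}

# corpus-level affect: preprocessed corpus -> per-user affect data frame
.corpus_affect <- function(pcorpus, lexicon) {
  .check_cols(pcorpus, c("user_id", "tokens"), "preprocessed corpus")
  sc <- score_status(pcorpus$tokens, lexicon)
  out <- do.call(rbind, lapply(split(sc$valence_sum, pcorpus$user_id),
                               user_affect))
  out <- cbind(user_id = rownames(out), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$user_id), , drop = FALSE]
}

#' Correlation matrix of affect features and self-reported SWL
#'
#' Pearson correlations, with two-sided p-values, among self-reported SWL and
#' the four affect features, on users present in both inputs. Constant columns
#' yield `NA` (undefined), never a silent zero.
#'
#' @param affect per-user affect data frame (from [user_affect()] rows bound
#'   together, with a `user_id` column).
#' @param outcomes data frame with `user_id` and `swl`.
#' @return list with `r` and `p` matrices (variables: swl, mean_sentiment,
#'   pos_freq, neg_freq, pos_neg_ratio) and `n`, the number of users used.
#' @export
affect_swl_correlations <- function(affect, outcomes) {
  .check_cols(affect, c("user_id", "mean_sentiment", "pos_freq", "neg_freq",
                        "pos_neg_ratio"), "affect features")
  .check_cols(outcomes, c("user_id", "swl"), "outcomes")
  m <- merge(affect, outcomes[, c("user_id", "swl")], by = "user_id")
  if (nrow(m) < 3L) .fail("need at least 3 users with both affect and SWL")
  vars <- c("swl", "mean_sentiment", "pos_freq", "neg_freq", "pos_neg_ratio")
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    ct <- suppressWarnings(.cor_test(m[[vars[i]]], m[[vars[j]]]))
    r[i, j] <- ct$r; p[i, j] <- ct$p
  }
  list(r = r, p = p, n = nrow(m))
}
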