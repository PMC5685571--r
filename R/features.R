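#' Concatenate each user's statuses into one document
#'
#' Topic and category scoring operate on one bag of tokens per user: the
#' concatenation of all the user's (preprocessed) status updates, together
#' with the user's status count, which is the normalization unit shared with
#' the affect features.
#'
#' @param pcorpus preprocessed corpus (columns `user_id`, `tokens`).
#' @return named list of documents, one per user (sorted by user id); each is
#'   a list with `tokens` (character vector), `n_statuses`, `n_words`.
#' @export
user_documents <- function(pcorpus) {
  .check_cols(pcorpus, c("user_id", "tokens"), "preprocessed corpus")
  flat <- unlist(pcorpus$tokens, use.names = FALSE)
  uidx <- rep.int(pcorpus$user_id, lengths(pcorpus$tokens))
  toks <- split(flat, uidx)
  nst <- table(pcorpus$user_id)
  ids <- sort(unique(pcorpus$user_id))
  out <- lapply(ids, function(u) {
    tk <- toks[[u]]
    if (is.null(tk)) tk <- character(0)
    list(user_id = u, tokens = tk, n_statuses = as.integer(nst[[u]]),
         n_words = length(tk))
  })
  names(out) <- ids
  out
}

#' Closed-vocabulary category counts for one document
#'
#' Counts document tokens falling in each category's word set. The normalized
#' value divides by the user's status count — the same convention as the
#' affect features, chosen because status lengths are too uneven for a
#' word-count denominator; raw counts are returned alongside.
#'
#' @param doc a document from [user_documents()].
#' @param category_lexicon data frame (`category`, `word`).
#' @return data frame with `category`, `count`, `normalized`.
#' @export
category_counts <- function(doc, category_lexicon) {
  .check_cols(category_lexicon, c("category", "word"), "category lexicon")
  cats <- sort(unique(category_lexicon$category))
  cat_of <- split(category_lexicon$word, category_lexicon$category)
  cnt <- vapply(cats, function(cc) sum(doc$tokens %in% cat_of[[cc]]),
                numeric(1))
  data.frame(category = cats, count = unname(cnt),
             normalized = unname(cnt) / doc$n_statuses,
             stringsAsFactors = FALSE)
}

#' Topic scores by word counting
#'
#' The word-count scoring rule for a truncated topic table: each use of a word
#' increases the user's score for every topic whose list contains the word by
#' exactly 1, regardless of the tabulated p(t|w). A word listed under six
#' topics therefore credits all six; a word listed once credits only its
#' topic. This deliberately flattens the spread that the tabulated
#' probabilities would induce (see [topic_probability_scores()] for the
#' probability-weighted alternative it is compared against).
#'
#' @param doc a document from [user_documents()].
#' @param topic_table data frame (`topic_id`, `word`, `p_tw`).
#' @return named numeric vector of per-topic scores (all listed topics).
#' @export
topic_wordcount_scores <- function(doc, topic_table) {
  .check_cols(topic_table, c("topic_id", "word", "p_tw"), "topic table")
  topics <- sort(unique(topic_table$topic_id))
  out <- stats::setNames(numeric(length(topics)), topics)
  if (!length(doc$tokens)) return(out)
  wc <- table(doc$tokens)
  hit <- topic_table$word %in% names(wc)
  if (any(hit)) {
    add <- as.numeric(wc[topic_table$word[hit]])
    agg <- rowsum(add, topic_table$topic_id[hit])
    out[rownames(agg)] <- agg[, 1]
  }
  out
}

#' Topic scores by truncated-table probabilities
#'
#' The probability scoring rule: p(t|u) = sum over words w listed under topic
#' t of p(t|w) * p(w|u), where p(w|u) is the word's relative frequency in the
#' user's document. Because the table is truncated, most words contribute to
#' only a few topics, and words appearing in a single topic carry p(t|w) = 1,
#' which can overstate their topical weight — the pathology that motivates
#' the word-count alternative.
#'
#' @inheritParams topic_wordcount_scores
#' @return named numeric vector of per-topic scores.
#' @export
topic_probability_scores <- function(doc, topic_table) {
  .check_cols(topic_table, c("topic_id", "word", "p_tw"), "topic table")
  if (!length(doc$tokens))
    .fail("document for user %s has zero words; p(w|u) is undefined",
          doc$user_id)
  topics <- sort(unique(topic_table$topic_id))
  out <- stats::setNames(numeric(length(topics)), topics)
  wc <- table(doc$tokens)
  hit <- topic_table$word %in% names(wc)
  if (any(hit)) {
    pwu <- as.numeric(wc[topic_table$word[hit]]) / doc$n_words
    agg <- rowsum(topic_table$p_tw[hit] * pwu, topic_table$topic_id[hit])
    out[rownames(agg)] <- agg[, 1]
  }
  out
}

#' Spread of topic scores under the two scoring rules
#'
#' For one document, the ratio between the highest and lowest strictly
#' positive topic score under the word-count rule and under the probability
#' rule. The word-count rule is expected to compress this spread on tables
#' with truncation pathologies — a tested property, not an assumption.
#'
#' @inheritParams topic_wordcount_scores
#' @return named numeric vector `c(ratio_wordcount, ratio_probability)`.
#' @export
compare_scoring_ratio <- function(doc, topic_table) {
  wcs <- topic_wordcount_scores(doc, topic_table)
  pbs <- topic_probability_scores(doc, topic_table)
  ratio <- function(s) {
    s <- s[s > 0]
    if (length(s) < 2L)
      .fail("fewer than 2 positive topic scores; spread ratio undefined")
    max(s) / min(s)
  }
  c(ratio_wordcount = ratio(wcs), ratio_probability = ratio(pbs))
}

#' Assemble the user-by-feature matrix
#'
#' Column-binds the affect features, category counts and topic scores for a
#' common user set into one numeric matrix with namespaced column names
#' (`affect:*`, `cat:*`, `topic:*`), rows sorted by user id. Category and
#' topic values are normalized by the user's status count; topic scores use
#' the word-count rule. Internally computed with sparse matrix algebra; the
#' per-document operations above define the semantics and serve as its
#' oracle.
#'
#' @param pcorpus preprocessed corpus (columns `user_id`, `tokens`).
#' @param lexicon valence lexicon.
#' @param topic_table truncated topic table.
#' @param category_lexicon category lexicon.
#' @param normalize_topics divide topic scores by status count (default TRUE).
#' @return list with `X` (numeric matrix, rownames = user ids), `affect`
#'   (per-user affect data frame), `n_statuses` (named vector).
#' @export
build_feature_matrix <- function(pcorpus, lexicon, topic_table,
                                 category_lexicon, normalize_topics = TRUE) {
  .check_cols(pcorpus, c("user_id", "tokens"), "preprocessed corpus")
  affect <- .corpus_affect(pcorpus, lexicon)
  ids <- affect$user_id
  nst <- stats::setNames(affect$n_statuses, ids)

  flat <- unlist(pcorpus$tokens, use.names = FALSE)
  uidx <- rep.int(match(pcorpus$user_id, ids), lengths(pcorpus$tokens))
  vocab <- sort(unique(c(topic_table$word, category_lexicon$word)))
  widx <- match(flat, vocab)
  keep <- !is.na(widx)
  U <- Matrix::sparseMatrix(i = uidx[keep], j = widx[keep],
                            x = rep(1, sum(keep)),
                            dims = c(length(ids), length(vocab)),
                            dimnames = list(ids, vocab))

  topics <- sort(unique(topic_table$topic_id))
  Tinc <- Matrix::sparseMatrix(
    i = match(topic_table$word, vocab),
    j = match(topic_table$topic_id, topics),
    x = rep(1, nrow(topic_table)),
    dims = c(length(vocab), length(topics)),
    dimnames = list(vocab, topics))
  topic_scores <- as.matrix(U %*% Tinc)
  if (normalize_topics) topic_scores <- topic_scores / nst[ids]

  cats <- sort(unique(category_lexicon$category))
  Cinc <- Matrix::sparseMatrix(
    i = match(category_lexicon$word, vocab),
    j = match(category_lexicon$category, cats),
    x = rep(1, nrow(category_lexicon)),
    dims = c(length(vocab), length(cats)),
    dimnames = list(vocab, cats))
  cat_scores <- as.matrix(U %*% Cinc) / nst[ids]

  A <- as.matrix(affect[, c("mean_sentiment", "pos_freq", "neg_freq",
                            "pos_neg_ratio")])
  X <- cbind(A, cat_scores, topic_scores)
  colnames(X) <- c(paste0("affect:", colnames(A)),
                   paste0("cat:", cats), paste0("topic:", topics))
  rownames(X) <- ids
  if (anyNA(X)) .fail("feature matrix contains missing entries")
  list(X = X, affect = affect, n_statuses = nst)
}

# subset a feature matrix to aligned outcome users, failing loudly on mismatch
.align_users <- function(X, outcomes) {
  missing_x <- setdiff(outcomes$user_id, rownames(X))
  if (length(missing_x))
    .fail("users missing from feature matrix: %s",
          paste(utils::head(missing_x, 5), collapse = ", "))
  ids <- intersect(rownames(X), outcomes$user_id)
  list(X = X[ids, , drop = FALSE],
       y = outcomes$swl[match(ids, outcomes$user_id)],
       ids = ids)
}
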