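#' Default emoticon-to-word map
#'
#' Social-media "smileys" are punctuation sequences carrying valence. Before
#' punctuation is stripped they are converted to word tokens so their affect
#' signal survives cleaning: variants such as `":)"`, `":-)"` and `"=)"` all
#' collapse to the single concept token `"happyface"`, and frowns to
#' `"sadface"`. Only the `":-)"`/`":-("` mappings are canonical; the rest of
#' the inventory is an editable convenience and can be replaced by any map in
#' the same two-column format.
#'
#' @return data frame with columns `pattern` (literal punctuation sequence)
#'   and `replacement` (lowercase word token).
#' @export
#' @examples
#' default_smiley_map()
default_smiley_map <- function() {
  data.frame(
    pattern = c(":-)", ":-(", ":)", ":(", "=)", "=(", ":-D", ":D",
                ";-)", ";)", ":'(", "<3"),
    replacement = c("happyface", "sadface", "happyface", "sadface",
                    "happyface", "sadface", "happyface", "happyface",
                    "happyface", "happyface", "sadface", "happyface"),
    stringsAsFactors = FALSE
  )
}

#' Convert emoticons to word tokens
#'
#' Replaces every occurrence of a mapped punctuation pattern with its word
#' token, padded with spaces. Patterns are applied longest-first so that
#' `":-)"` wins over `":)"`. Idempotent on text without emoticons (and on its
#' own output, since replacements are alphabetic).
#'
#' @param text character vector of raw status text.
#' @param map smiley map (`pattern`, `replacement`); default
#'   [default_smiley_map()].
#' @return character vector with emoticons replaced by tokens.
#' @export
#' @examples
#' convert_smileys("great day :-)")
convert_smileys <- function(text, map = default_smiley_map()) {
  .check_cols(map, c("pattern", "replacement"), "smiley map")
  ord <- order(nchar(map$pattern), decreasing = TRUE)
  for (i in ord) {
    text <- gsub(map$pattern[i], paste0(" ", map$replacement[i], " "),
                 text, fixed = TRUE)
  }
  text
}

#' Clean status text
#'
#' Removes hyperlinks (tokens starting with `http://`, `https://` or `www.`),
#' digits and punctuation, then lowercases and collapses whitespace. Intended
#' to run after [convert_smileys()] — emoticons are made of punctuation and
#' would otherwise be destroyed here.
#'
#' @param text character vector.
#' @return cleaned character vector containing only `[a-z ]`.
#' @export
#' @examples
#' clean_status("see http://x.co at 9pm!!")
clean_status <- function(text) {
  text <- gsub("(^|\\s)(https?://|www\\.)\\S*", " ", text, perl = TRUE)
  text <- gsub("[0-9]+", "", text)
  text <- gsub("[^A-Za-z ]+", " ", text)
  text <- tolower(text)
  text <- gsub("\\s+", " ", text)
  trimws(text)
}

#' Tokenize cleaned text
#'
#' Whitespace split, order preserving; an empty string yields a zero-length
#' token vector. Duplicated words are preserved (all downstream scoring counts
#' tokens, not types).
#'
#' @param text a single cleaned string.
#' @return character vector of tokens (possibly empty).
#' @export
tokenize_status <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || trimws(text) == "") return(character(0))
  strsplit(trimws(text), "\\s+")[[1]]
}

#' Preprocess a status-update corpus
#'
#' Full cleaning pass in the fixed order: URL removal, digit removal, emoticon
#' conversion, punctuation removal, lowercasing, tokenization. URLs go first so
#' that `":/"` inside a hyperlink never matches an emoticon; emoticon
#' conversion precedes punctuation stripping because emoticons are made of
#' punctuation. Stop words are deliberately kept: the word and topic lists
#' consumed downstream already account for them.
#'
#' @param corpus data frame with columns `user_id`, `text`.
#' @param smileys smiley map, default [default_smiley_map()].
#' @return the corpus with an added list-column `tokens` (character vectors,
#'   lowercased, free of digits/punctuation/URLs).
#' @export
preprocess_corpus <- function(corpus, smileys = default_smiley_map()) {
  .check_cols(corpus, c("user_id", "text"), "corpus")
  txt <- gsub("(^|\\s)(https?://|www\\.)\\S*", " ", corpus$text, perl = TRUE)
  txt <- gsub("[0-9]+", "", txt)
  txt <- convert_smileys(txt, smileys)
  txt <- tolower(gsub("[^A-Za-z ]+", " ", txt))
  txt <- trimws(gsub("\\s+", " ", txt))
  corpus$tokens <- strsplit(txt, " ", fixed = TRUE)
  empty <- txt == ""
  if (any(empty)) corpus$tokens[empty] <- list(character(0))
  corpus
}

#' Retain only users with enough statuses
#'
#' Users posting fewer than `min_statuses` updates carry too little text for
#' stable per-user features and are dropped before any scoring (the same
#' retention rule the generator applies).
#'
#' @param corpus (possibly preprocessed) corpus data frame.
#' @param min_statuses retention threshold, default 30.
#' @return the filtered corpus; fails if no user survives.
#' @export
filter_min_statuses <- function(corpus, min_statuses = 30) {
  .check_cols(corpus, "user_id", "corpus")
  n <- table(corpus$user_id)
  keep <- names(n)[n >= min_statuses]
  if (!length(keep))
    .fail("retention filter (>= %d statuses) removed all %d users",
          min_statuses, length(n))
  out <- corpus[corpus$user_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
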