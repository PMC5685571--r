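#' Read and write the plain-text resource formats
#'
#' All resources are small delimited text files:
#' \itemize{
#'   \item corpus: tab-separated `user_id<TAB>status_text`, one status per line;
#'   \item outcomes: CSV `user_id,swl,cesd` (`cesd` may be empty);
#'   \item valence lexicon: CSV `word,valence` with valence in \{+1, -1\};
#'   \item topic table: CSV `topic_id,word,p_tw` with `p_tw` in (0, 1];
#'   \item category lexicon: CSV `category,word`;
#'   \item activity lexicon: CSV `activity,word` with optional
#'     `rating_a,rating_b` columns holding two raters' labels per term;
#'   \item smiley map: CSV `pattern,replacement`, applied longest-pattern-first.
#' }
#'
#' Readers validate the schema and return plain data frames; writers
#' round-trip losslessly through the readers.
#'
#' @param path file path.
#' @name swb_io
NULL

#' @rdname swb_io
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) .fail("corpus file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          col.names = c("user_id", "text"),
                          colClasses = "character", blank.lines.skip = FALSE)
  df <- df[df$user_id != "", , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname swb_io
#' @param corpus data frame with columns `user_id`, `text`.
#' @export
write_corpus <- function(corpus, path) {
  .check_cols(corpus, c("user_id", "text"), "corpus")
  txt <- gsub("[\t\n\r]", " ", corpus$text)
  .write_lines(paste(corpus$user_id, txt, sep = "\t"), path)
}

#' @rdname swb_io
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, colClasses = c(user_id = "character"))
  .check_cols(df, c("user_id", "swl"), "outcomes")
  if (!"cesd" %in% names(df)) df$cesd <- NA_real_
  df
}

#' @rdname swb_io
#' @param outcomes data frame with columns `user_id`, `swl` and optionally `cesd`.
#' @export
write_outcomes <- function(outcomes, path) {
  .check_cols(outcomes, c("user_id", "swl"), "outcomes")
  if (!"cesd" %in% names(outcomes)) outcomes$cesd <- NA_real_
  utils::write.csv(outcomes[, c("user_id", "swl", "cesd")], path,
                   row.names = FALSE, quote = FALSE)
}

#' @rdname swb_io
#' @export
read_valence_lexicon <- function(path) {
  df <- utils::read.csv(path, colClasses = c(word = "character"))
  .check_cols(df, c("word", "valence"), "valence lexicon")
  if (!all(df$valence %in% c(-1, 1)))
    .fail("valence lexicon: valence must be +1 or -1")
  if (anyDuplicated(df$word))
    .fail("valence lexicon: duplicated word(s), positive and negative sets must be disjoint")
  df
}

#' @rdname swb_io
#' @param lexicon valence-lexicon data frame (`word`, `valence`).
#' @export
write_valence_lexicon <- function(lexicon, path) {
  .check_cols(lexicon, c("word", "valence"), "valence lexicon")
  utils::write.csv(lexicon[, c("word", "valence")], path,
                   row.names = FALSE, quote = FALSE)
}

#' @rdname swb_io
#' @export
read_topic_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c(word = "character"))
  .check_cols(df, c("topic_id", "word", "p_tw"), "topic table")
  if (any(df$p_tw <= 0 | df$p_tw > 1)) .fail("topic table: p_tw must lie in (0, 1]")
  df$topic_id <- as.character(df$topic_id)
  df
}

#' @rdname swb_io
#' @param table topic-table data frame (`topic_id`, `word`, `p_tw`).
#' @export
write_topic_table <- function(table, path) {
  .check_cols(table, c("topic_id", "word", "p_tw"), "topic table")
  utils::write.csv(table[, c("topic_id", "word", "p_tw")], path,
                   row.names = FALSE, quote = FALSE)
}

#' @rdname swb_io
#' @export
read_category_lexicon <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  .check_cols(df, c("category", "word"), "category lexicon")
  df
}

#' @rdname swb_io
#' @export
read_activity_lexicon <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  .check_cols(df, c("activity", "word"), "activity lexicon")
  df
}

#' @rdname swb_io
#' @param lex category or activity lexicon data frame.
#' @export
write_category_lexicon <- function(lex, path) {
  .check_cols(lex, c("category", "word"), "category lexicon")
  utils::write.csv(lex, path, row.names = FALSE, quote = FALSE)
}

#' @rdname swb_io
#' @export
write_activity_lexicon <- function(lex, path) {
  .check_cols(lex, c("activity", "word"), "activity lexicon")
  utils::write.csv(lex, path, row.names = FALSE, quote = FALSE)
}

#' @rdname swb_io
#' @export
read_smiley_map <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", quote = "\"")
  .check_cols(df, c("pattern", "replacement"), "smiley map")
  df
}

.write_lines <- function(lines, path) {
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) .fail("cannot write to path: %s", path))
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
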