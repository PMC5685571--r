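#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: heavy-tailed per-user status counts with a retention filter at 30
#' statuses, positively skewed sentiment (most users post more positive than
#' negative updates), a latent satisfaction-with-life (SWL) trait that drives
#' positive/negative word emission and the usage of a subset of "informative"
#' topics, a noisy self-reported SWL, and a CES-D depression score negatively
#' coupled to SWL for a subset of users.
#'
#' Defaults encode the study conditions: SWL mean 4.2 on the 1--7 five-item
#' scale, a negative-binomial status count with mean 180 (so that roughly
#' 15--20% of users fall under the 30-status retention threshold), status
#' lengths mixing ~11% short (<4 words), ~65% medium (4--20) and ~24% long
#' (>20) updates, and emission effects calibrated once so that the generated
#' affect/SWL correlation structure matches the observed one (sentiment ~0.21,
#' negative frequency ~-0.23, positive frequency ~0.08) — see the methods
#' vignette for the calibration account.
#'
#' @param n_users users to draw before the retention filter.
#' @param mean_statuses negative-binomial mean of per-user status counts.
#' @param nb_size negative-binomial size (overdispersion; smaller = heavier tail).
#' @param min_statuses retention threshold (users below are discarded).
#' @param swl_mean,swl_sd latent SWL truncated-normal parameters on [1, 7].
#' @param noise_sd measurement noise added to latent SWL to give the
#'   self-reported SWL.
#' @param n_topics,words_per_topic topic-table dimensions (`words_per_topic`
#'   at most 20, matching the truncated published-table format).
#' @param n_informative_topics number of topics whose usage is coupled to SWL.
#' @param topic_effect per-SWL-unit log-multiplier on informative-topic usage.
#' @param affect_effect per-SWL-unit shift in positive-word emission
#'   probability.
#' @param neg_affect_gain multiplier on `affect_effect` for the (negative)
#'   link from SWL to negative-word emission — negative affect frequency is
#'   the more SWL-diagnostic channel, as in the observed correlation
#'   structure.
#' @param base_pos,base_neg baseline per-token emission probabilities of
#'   positive/negative valence words.
#' @param user_pos_sd,user_neg_sd between-user SD of stable emission
#'   heterogeneity (limits attainable trait correlations, as in real text).
#' @param base_informative,base_background total per-token probability of
#'   informative-topic and background-topic words.
#' @param user_topic_sd between-user SD of informative-topic appetite (shared
#'   across informative topics, inducing the correlated-feature structure an
#'   elastic net must cope with).
#' @param base_style,style_effect,user_style_sd the "style word" channel:
#'   two 30-word vocabularies (swear-like and achievement-like) emitted at a
#'   combined base rate `base_style`, with log-linear SWL links of opposite
#'   sign (`style_effect`) and per-user appetite SD `user_style_sd`. Style
#'   words appear in the category lexicon but not in the topic table, so the
#'   category channel carries trait signal of its own, as real
#'   closed-vocabulary categories do.
#' @param cesd_slope slope of CES-D on latent SWL (negative).
#' @param cesd_noise_sd,cesd_mean,cesd_range CES-D noise SD, center, and
#'   clamping range (default the standard 0--60 instrument range).
#' @param cesd_fraction fraction of users with a CES-D score.
#' @param n_pos_words,n_neg_words,n_filler_words vocabulary sizes.
#' @param smiley_prob probability a valence token is rendered as an emoticon
#'   in the raw text (exercising the preprocessing stage).
#' @param activity_prob probability a status is "about" one of the activities
#'   in the activity lexicon.
#' @param seed master seed; all stages derive from it via [stage_seed()].
#' @return a list of class `swb_sim_config`.
#' @export
swb_sim_config <- function(n_users = 2500,
                           mean_statuses = 180,
                           nb_size = 1,
                           min_statuses = 30,
                           swl_mean = 4.2,
                           swl_sd = 1.3,
                           noise_sd = 0.6,
                           n_topics = 200,
                           words_per_topic = 15,
                           n_informative_topics = 10,
                           topic_effect = 0.10,
                           affect_effect = 0.002,
                           neg_affect_gain = 3,
                           base_pos = 0.070,
                           base_neg = 0.038,
                           user_pos_sd = 0.024,
                           user_neg_sd = 0.030,
                           base_informative = 0.04,
                           base_background = 0.20,
                           user_topic_sd = 0.10,
                           base_style = 0.02,
                           style_effect = 0.08,
                           user_style_sd = 0.10,
                           cesd_slope = -4,
                           cesd_noise_sd = 8,
                           cesd_mean = 18,
                           cesd_range = c(0, 60),
                           cesd_fraction = 0.148,
                           n_pos_words = 150,
                           n_neg_words = 150,
                           n_filler_words = 400,
                           smiley_prob = 0.15,
                           activity_prob = 0.08,
                           seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_users >= 1, cfg$mean_statuses > 0, cfg$min_statuses >= 1,
            cfg$swl_sd > 0, cfg$noise_sd > 0,
            cfg$words_per_topic <= 20, cfg$words_per_topic >= 1,
            cfg$n_informative_topics <= cfg$n_topics,
            cfg$cesd_slope < 0, cfg$n_pos_words >= 1, cfg$n_neg_words >= 1)
  class(cfg) <- "swb_sim_config"
  cfg
}

# deterministic alphabetic word ids: no digits, so preprocessing cannot
# mangle synthetic vocabulary
.make_words <- function(prefix, n) {
  if (n <= 0) return(character(0))
  idx <- seq_len(n) - 1L
  a <- letters[idx %/% 676L + 1L]
  b <- letters[(idx %/% 26L) %% 26L + 1L]
  c3 <- letters[idx %% 26L + 1L]
  paste0(prefix, a, b, c3)
}

#' Generate a synthetic valence lexicon
#'
#' Stand-in for a published valence word list augmented with emoticon tokens.
#' Contains exactly `n_pos` words of valence +1 (always including
#' `"happyface"`) and `n_neg` of valence -1 (always including `"sadface"`);
#' the two sign sets are disjoint by construction.
#'
#' @param n_pos,n_neg counts per sign (each at least 1).
#' @param seed seed (row order shuffle; contents are deterministic).
#' @return valence-lexicon data frame (`word`, `valence`).
#' @export
#' @examples
#' sim_valence_lexicon(3, 2)
sim_valence_lexicon <- function(n_pos, n_neg, seed = 1) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  pos <- c("happyface", .make_words("pos", n_pos - 1L))
  neg <- c("sadface", .make_words("neg", n_neg - 1L))
  df <- data.frame(word = c(pos, neg),
                   valence = rep(c(1, -1), c(n_pos, n_neg)),
                   stringsAsFactors = FALSE)
  set.seed(stage_seed(seed, 11))
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Generate a synthetic truncated topic table
#'
#' Emulates a thresholded word--topic probability table: each topic lists at
#' most `words_per_topic` (word, p(t|w)) pairs. The truncation pathology is
#' planted deliberately: a fraction of words appear in exactly one topic and
#' carry p(t|w) = 1 there, while shared words appear in 2--6 topics with
#' probabilities summing to at most 1 across their topics.
#'
#' @param n_topics,words_per_topic table dimensions (`words_per_topic` <= 20).
#' @param seed seed.
#' @param shared_fraction target fraction of table slots filled by words
#'   shared between topics.
#' @return topic-table data frame (`topic_id`, `word`, `p_tw`).
#' @export
sim_topic_table <- function(n_topics, words_per_topic, seed = 1,
                            shared_fraction = 0.3) {
  stopifnot(n_topics >= 1, words_per_topic >= 1, words_per_topic <= 20,
            shared_fraction >= 0, shared_fraction < 1)
  set.seed(stage_seed(seed, 12))
  topic_ids <- paste0("t", formatC(seq_len(n_topics), width = 4, flag = "0"))
  capacity <- rep(words_per_topic, n_topics)
  rows_topic <- character(0); rows_word <- character(0); rows_p <- numeric(0)

  # shared words first (need >= 2 topics with spare capacity)
  target_shared <- floor(n_topics * words_per_topic * shared_fraction)
  shared_slots <- 0L
  widx <- 0L
  while (shared_slots < target_shared) {
    open <- which(capacity > 0L)
    if (length(open) < 2L) break
    k <- sample(2:min(6L, length(open)), 1L)
    tsel <- sample(open, k)
    widx <- widx + 1L
    w <- .make_words("shw", widx)[widx] # unique shared word
    total <- stats::runif(1, 0.6, 1.0)
    p <- as.vector(stats::rgamma(k, 1) + 0.05)
    p <- p / sum(p) * total
    rows_topic <- c(rows_topic, topic_ids[tsel])
    rows_word <- c(rows_word, rep(w, k))
    rows_p <- c(rows_p, p)
    capacity[tsel] <- capacity[tsel] - 1L
    shared_slots <- shared_slots + k
  }

  # exclusive words fill remaining capacity; p(t|w) = 1 (truncation artifact)
  n_excl <- sum(capacity)
  if (n_excl > 0) {
    ew <- .make_words("top", n_excl)
    et <- rep(topic_ids, capacity)
    rows_topic <- c(rows_topic, et)
    rows_word <- c(rows_word, ew)
    rows_p <- c(rows_p, rep(1, n_excl))
  }
  df <- data.frame(topic_id = rows_topic, word = rows_word, p_tw = rows_p,
                   stringsAsFactors = FALSE)
  df <- df[order(df$topic_id, df$word), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Generate a synthetic closed-vocabulary category lexicon
#'
#' Stand-in for a psycholinguistic category resource. Categories overlap the
#' other vocabularies the way real closed-vocabulary resources do:
#' `posemo`/`negemo` draw on the valence lexicon (affect signal), a few
#' "topical" categories draw on topic-table vocabulary (including the
#' SWL-informative topics, so the category channel carries weak trait signal
#' of its own), and the remainder draw on neutral filler words.
#'
#' @param lexicon valence lexicon (used for posemo/negemo).
#' @param topic_table topic table whose vocabulary seeds topical categories.
#' @param informative_topics topic ids treated as SWL-informative.
#' @param filler character vector of neutral vocabulary.
#' @param style_sets optional named list of word vectors included verbatim as
#'   categories (the generator passes its swear/achievement style sets).
#' @param n_categories number of categories (>= 2).
#' @param words_per_category words per category.
#' @param seed seed.
#' @return category-lexicon data frame (`category`, `word`).
#' @export
sim_category_lexicon <- function(lexicon, topic_table, informative_topics,
                                 filler, style_sets = NULL,
                                 n_categories = 20,
                                 words_per_category = 20, seed = 1) {
  stopifnot(n_categories >= 2)
  set.seed(stage_seed(seed, 13))
  pos <- lexicon$word[lexicon$valence > 0]
  neg <- lexicon$word[lexicon$valence < 0]
  inf_words <- unique(topic_table$word[topic_table$topic_id %in%
                                         informative_topics])
  bg_words <- setdiff(unique(topic_table$word), inf_words)
  cats <- list(
    posemo = sample(pos, min(words_per_category, length(pos))),
    negemo = sample(neg, min(words_per_category, length(neg)))
  )
  if (!is.null(style_sets)) cats <- c(cats, style_sets)
  extra <- max(0L, n_categories - 2L)
  if (extra > 0) {
    nm <- paste0("cat", formatC(seq_len(extra), width = 2, flag = "0"))
    for (i in seq_len(extra)) {
      pool <- if (i <= 2 && length(inf_words)) {
        # topical categories touching informative vocabulary
        c(sample(inf_words, min(words_per_category %/% 2, length(inf_words))),
          sample(bg_words, min(words_per_category %/% 2, length(bg_words))))
      } else if (i <= 6 && length(bg_words)) {
        sample(bg_words, min(words_per_category, length(bg_words)))
      } else {
        sample(filler, min(words_per_category, length(filler)))
      }
      cats[[nm[i]]] <- unique(pool)
    }
  }
  data.frame(category = rep(names(cats), lengths(cats)),
             word = unlist(cats, use.names = FALSE),
             stringsAsFactors = FALSE)
}

# activity -> affect loading used by the generator (shift of positive-word
# emission for statuses about the activity; negative emission shifts by the
# opposite amount)
.activity_loadings <- c(
  religion = 0.040, holiday = 0.030, talk_to_friend = 0.030,
  chores = 0.022, family = 0.020, meal = 0.020,
  school = -0.012, maths = -0.018, death_disease = -0.050
)

#' Synthetic activity lexicon with rater labels
#'
#' A hand-built activity-to-word list emulating the supplementary activity
#' table of an experience-sampling comparison: everyday activities (religion,
#' holiday, talking to friends, chores, family, meals, school, maths) plus a
#' death/disease topic whose statuses the generator couples to negative
#' valence. Each term carries two synthetic rater labels
#' (`relevant`/`irrelevant`) whose agreement structure gives Cohen's kappa of
#' 0.36, the reported inter-rater reliability for the real table.
#'
#' @return activity-lexicon data frame (`activity`, `word`, `rating_a`,
#'   `rating_b`).
#' @export
sim_activity_lexicon <- function() {
  path <- system.file("extdata", "activity_lexicon_synthetic.csv",
                      package = "swbprofiler", mustWork = TRUE)
  read_activity_lexicon(path)
}

# truncated-normal draw via inverse CDF
.rtnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic user corpus with planted ground truth
#'
#' Draws latent SWL from a truncated normal on [1, 7], per-user status counts
#' from a negative binomial (users under the retention threshold are
#' discarded), and emits each status as a bag of tokens mixing valence words
#' (positive emission increasing in latent SWL), informative- and
#' background-topic words, activity words with activity-specific affect
#' shifts, emoticons, and neutral filler. Self-reported SWL is the latent
#' trait plus measurement noise; CES-D is a negative linear function of latent
#' SWL plus noise, present for a subset of users.
#'
#' @param cfg a [swb_sim_config()].
#' @param raw_text if `TRUE` (default) statuses are rendered as raw text with
#'   emoticons, occasional hyperlinks, digits and punctuation (exercising the
#'   preprocessing stage); if `FALSE` the corpus carries a clean `tokens`
#'   list-column instead, which is much faster for simulation studies.
#' @return a list of class `swb_sim` with elements `corpus` (data frame
#'   `user_id`, `status_id`, `text` and/or `tokens`), `truth` (data frame
#'   `user_id`, `swl_latent`, `swl_self`, `cesd`, `p_pos`, `n_statuses`),
#'   `lexicon`, `topic_table`, `category_lexicon`, `activity_lexicon`,
#'   `informative_topics`, `config`.
#' @export
sim_corpus <- function(cfg = swb_sim_config(), raw_text = TRUE) {
  stopifnot(inherits(cfg, "swb_sim_config"))

  lexicon <- sim_valence_lexicon(cfg$n_pos_words, cfg$n_neg_words, cfg$seed)
  ttab <- sim_topic_table(cfg$n_topics, cfg$words_per_topic, cfg$seed)
  filler <- .make_words("fill", cfg$n_filler_words)
  style_sets <- list(swear = .make_words("swr", 30),
                     achieve = .make_words("ach", 30))
  topic_ids_all <- sort(unique(ttab$topic_id))
  category_lexicon <- sim_category_lexicon(
    lexicon, ttab, topic_ids_all[seq_len(cfg$n_informative_topics)],
    filler, style_sets = style_sets, seed = cfg$seed)
  activity_lexicon <- sim_activity_lexicon()

  topic_ids <- sort(unique(ttab$topic_id))
  informative <- topic_ids[seq_len(cfg$n_informative_topics)]

  ## --- per-user traits ------------------------------------------------
  set.seed(stage_seed(cfg$seed, 1))
  n <- cfg$n_users
  swl_lat <- .rtnorm(n, cfg$swl_mean, cfg$swl_sd, 1, 7)
  swl_self <- pmin(7, pmax(1, swl_lat + stats::rnorm(n, 0, cfg$noise_sd)))
  n_statuses <- stats::rnbinom(n, size = cfg$nb_size, mu = cfg$mean_statuses)

  keep <- which(n_statuses >= cfg$min_statuses)
  if (!length(keep))
    .fail(paste0("retention filter: all %d users have fewer than %d statuses",
                 " (mean_statuses = %g too low)"),
          n, cfg$min_statuses, cfg$mean_statuses)

  set.seed(stage_seed(cfg$seed, 2))
  cesd <- cfg$cesd_mean + cfg$cesd_slope * (swl_lat - cfg$swl_mean) +
    stats::rnorm(n, 0, cfg$cesd_noise_sd)
  cesd <- pmin(cfg$cesd_range[2], pmax(cfg$cesd_range[1], cesd))
  has_cesd <- stats::runif(n) < cfg$cesd_fraction
  cesd[!has_cesd] <- NA_real_

  dswl <- swl_lat - cfg$swl_mean
  p_pos <- pmin(0.4, pmax(0.002,
    cfg$base_pos + cfg$affect_effect * dswl +
      stats::rnorm(n, 0, cfg$user_pos_sd)))
  p_neg <- pmin(0.4, pmax(0.002,
    cfg$base_neg - cfg$affect_effect * cfg$neg_affect_gain * dswl +
      stats::rnorm(n, 0, cfg$user_neg_sd)))
  inf_mult <- exp(cfg$topic_effect * dswl + stats::rnorm(n, 0, cfg$user_topic_sd))
  swr_mult <- exp(-cfg$style_effect * dswl + stats::rnorm(n, 0, cfg$user_style_sd))
  ach_mult <- exp(cfg$style_effect * dswl + stats::rnorm(n, 0, cfg$user_style_sd))

  ## --- vocabulary layout ----------------------------------------------
  pos_words <- lexicon$word[lexicon$valence > 0]
  neg_words <- lexicon$word[lexicon$valence < 0]
  tw <- unique(ttab$word)
  # per-word emission weight within a topic block: uniform over topics in the
  # block, uniform over that topic's words; shared words accumulate
  wpt <- table(ttab$topic_id)[topic_ids]
  w_weight <- 1 / as.numeric(wpt)[match(ttab$topic_id, topic_ids)]
  inf_mask <- ttab$topic_id %in% informative
  inf_w <- tapply(w_weight[inf_mask], ttab$word[inf_mask], sum)
  bg_w <- tapply(w_weight[!inf_mask], ttab$word[!inf_mask], sum)
  inf_vocab <- names(inf_w); bg_vocab <- names(bg_w)
  act_words <- activity_lexicon$word
  act_of_word <- activity_lexicon$activity
  activities <- unique(act_of_word)
  loadings <- .activity_loadings[activities]
  loadings[is.na(loadings)] <- 0

  vocab <- c(pos_words, neg_words, inf_vocab, bg_vocab,
             style_sets$swear, style_sets$achieve, filler)
  seg <- rep(c("pos", "neg", "inf", "bg", "swr", "ach", "fill"),
             c(length(pos_words), length(neg_words), length(inf_vocab),
               length(bg_vocab), length(style_sets$swear),
               length(style_sets$achieve), length(filler)))
  w_within <- c(rep(1 / length(pos_words), length(pos_words)),
                rep(1 / length(neg_words), length(neg_words)),
                as.numeric(inf_w) / sum(inf_w),
                as.numeric(bg_w) / sum(bg_w),
                rep(1 / length(style_sets$swear), length(style_sets$swear)),
                rep(1 / length(style_sets$achieve), length(style_sets$achieve)),
                rep(1 / length(filler), length(filler)))
  seg_levels <- c("pos", "neg", "inf", "bg", "swr", "ach", "fill")
  seg_i <- match(seg, seg_levels)

  ## --- token emission ---------------------------------------------------
  set.seed(stage_seed(cfg$seed, 3))
  uid <- sprintf("u%05d", seq_len(n))
  out_user <- vector("list", length(keep))
  out_tokens <- vector("list", length(keep))
  out_sidx <- vector("list", length(keep))
  n_act <- length(activities)
  for (j in seq_along(keep)) {
    i <- keep[j]
    m <- n_statuses[i]
    stratum <- sample.int(3L, m, replace = TRUE, prob = c(0.11, 0.65, 0.24))
    len <- integer(m)
    len[stratum == 1L] <- sample(1:3, sum(stratum == 1L), replace = TRUE)
    len[stratum == 2L] <- sample(4:20, sum(stratum == 2L), replace = TRUE)
    len[stratum == 3L] <- sample(21:40, sum(stratum == 3L), replace = TRUE)

    p_inf_u <- cfg$base_informative * inf_mult[i]
    p_swr_u <- cfg$base_style / 2 * swr_mult[i]
    p_ach_u <- cfg$base_style / 2 * ach_mult[i]
    base_prob <- c(p_pos[i], p_neg[i], p_inf_u, cfg$base_background,
                   p_swr_u, p_ach_u)
    base_prob <- c(base_prob, max(0.01, 1 - sum(base_prob)))
    w_u <- w_within * base_prob[seg_i]

    toks <- sample(vocab, sum(len), replace = TRUE, prob = w_u)
    sidx <- rep.int(seq_len(m), len)

    # activity statuses: redraw with shifted valence, inject one activity word
    is_act <- stats::runif(m) < cfg$activity_prob
    if (any(is_act)) {
      acts <- sample.int(n_act, sum(is_act), replace = TRUE)
      ai <- which(is_act)
      for (k in seq_along(ai)) {
        s <- ai[k]; a <- acts[k]
        pp <- min(0.5, max(0.002, p_pos[i] + loadings[a]))
        pn <- min(0.5, max(0.002, p_neg[i] - loadings[a]))
        prob_a <- c(pp, pn, p_inf_u, cfg$base_background, p_swr_u, p_ach_u)
        prob_a <- c(prob_a, max(0.01, 1 - sum(prob_a)))
        w_a <- w_within * prob_a[seg_i]
        st <- sample(vocab, len[s], replace = TRUE, prob = w_a)
        st[sample.int(len[s], 1L)] <-
          sample(act_words[act_of_word == activities[a]], 1L)
        toks[sidx == s] <- st
      }
    }
    out_user[[j]] <- rep.int(uid[i], m)
    out_tokens[[j]] <- toks
    out_sidx[[j]] <- sidx
  }

  user_col <- unlist(out_user, use.names = FALSE)
  m_per <- n_statuses[keep]
  status_id <- unlist(lapply(m_per, seq_len), use.names = FALSE)
  corpus <- data.frame(user_id = user_col,
                       status_id = sprintf("%s_s%04d", user_col, status_id),
                       stringsAsFactors = FALSE)

  tok_flat <- unlist(out_tokens, use.names = FALSE)
  stat_flat <- unlist(mapply(function(s, off) s + off, out_sidx,
                             cumsum(c(0, m_per[-length(m_per)])),
                             SIMPLIFY = FALSE), use.names = FALSE)

  if (raw_text) {
    set.seed(stage_seed(cfg$seed, 4))
    # render a fraction of valence tokens as emoticons
    happy <- tok_flat == "happyface"
    sad <- tok_flat == "sadface"
    rh <- happy & stats::runif(length(tok_flat)) < cfg$smiley_prob
    rs <- sad & stats::runif(length(tok_flat)) < cfg$smiley_prob
    tok_render <- tok_flat
    if (any(rh)) tok_render[rh] <- sample(c(":-)", ":)", "=)"), sum(rh), TRUE)
    if (any(rs)) tok_render[rs] <- sample(c(":-(", ":(", ":'("), sum(rs), TRUE)
    text <- unname(vapply(split(tok_render, stat_flat), paste,
                          character(1), collapse = " "))
    nst <- nrow(corpus)
    bang <- stats::runif(nst) < 0.05
    text[bang] <- paste0(text[bang], "!!")
    url <- stats::runif(nst) < 0.01
    text[url] <- paste(text[url], "http://example.com/post")
    num <- stats::runif(nst) < 0.02
    text[num] <- paste(text[num], sample(1900:2099, sum(num), TRUE))
    corpus$text <- text
  } else {
    corpus$tokens <- unname(split(tok_flat, stat_flat))
  }

  truth <- data.frame(user_id = uid[keep],
                      swl_latent = swl_lat[keep],
                      swl_self = swl_self[keep],
                      cesd = cesd[keep],
                      p_pos = p_pos[keep],
                      n_statuses = n_statuses[keep],
                      stringsAsFactors = FALSE)

  structure(list(corpus = corpus, truth = truth, lexicon = lexicon,
                 topic_table = ttab, category_lexicon = category_lexicon,
                 activity_lexicon = activity_lexicon,
                 informative_topics = informative, config = cfg),
            class = "swb_sim")
}

#' @export
print.swb_sim <- function(x, ...) {
  cat("Synthetic SWB corpus\n")
  cat(sprintf("  users retained: %d of %d (>= %d statuses)\n",
              nrow(x$truth), x$config$n_users, x$config$min_statuses))
  cat(sprintf("  statuses: %d; topics: %d (%d informative); lexicon: %d words\n",
              nrow(x$corpus), x$config$n_topics,
              length(x$informative_topics), nrow(x$lexicon)))
  invisible(x)
}

#' Write a synthetic corpus bundle to a directory
#'
#' Emits every artifact in its documented plain-text format: `statuses.tsv`
#' (user_id, text), `outcomes.csv` (user_id, swl, cesd — self-reported
#' values), `truth.csv` (including the latent trait), `valence_lexicon.csv`,
#' `topic_table.csv`, `category_lexicon.csv`, `activity_lexicon.csv`. Files
#' round-trip losslessly through the package readers.
#'
#' @param sim an `swb_sim` object from [sim_corpus()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_swb_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "swb_sim"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    .fail("cannot create output directory: %s", dir)
  corp <- sim$corpus
  if (is.null(corp$text))
    corp$text <- vapply(corp$tokens, paste, character(1), collapse = " ")
  paths <- c(statuses = file.path(dir, "statuses.tsv"),
             outcomes = file.path(dir, "outcomes.csv"),
             truth = file.path(dir, "truth.csv"),
             lexicon = file.path(dir, "valence_lexicon.csv"),
             topics = file.path(dir, "topic_table.csv"),
             categories = file.path(dir, "category_lexicon.csv"),
             activities = file.path(dir, "activity_lexicon.csv"))
  write_corpus(corp, paths["statuses"])
  write_outcomes(data.frame(user_id = sim$truth$user_id,
                            swl = sim$truth$swl_self,
                            cesd = sim$truth$cesd), paths["outcomes"])
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE, quote = FALSE)
  write_valence_lexicon(sim$lexicon, paths["lexicon"])
  write_topic_table(sim$topic_table, paths["topics"])
  write_category_lexicon(sim$category_lexicon, paths["categories"])
  write_activity_lexicon(sim$activity_lexicon, paths["activities"])
  invisible(paths)
}
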