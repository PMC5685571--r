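# Shared fixtures, built in code. Heavyweight simulation results are cached
# per session so several test files can reuse them.

tiny_lexicon <- function() {
  data.frame(word = c("love", "great", "happyface", "bad", "awful", "sadface"),
             valence = c(1, 1, 1, -1, -1, -1), stringsAsFactors = FALSE)
}

make_doc <- function(tokens, n_statuses = 1, user_id = "u1") {
  list(user_id = user_id, tokens = tokens, n_statuses = n_statuses,
       n_words = length(tokens))
}

# naive reference scorers, independent of the package implementations
oracle_score <- function(tokens, lexicon) {
  s <- 0L
  pos <- lexicon$word[lexicon$valence > 0]
  neg <- lexicon$word[lexicon$valence < 0]
  for (tk in tokens) {
    if (tk %in% pos) s <- s + 1L
    if (tk %in% neg) s <- s - 1L
  }
  s
}

oracle_wordcount <- function(doc, tab) {
  topics <- sort(unique(tab$topic_id))
  out <- stats::setNames(numeric(length(topics)), topics)
  for (t in topics) {
    words <- tab$word[tab$topic_id == t]
    for (w in words) out[t] <- out[t] + sum(doc$tokens == w)
  }
  out
}

oracle_probability <- function(doc, tab) {
  topics <- sort(unique(tab$topic_id))
  out <- stats::setNames(numeric(length(topics)), topics)
  for (t in topics) {
    rows <- which(tab$topic_id == t)
    for (k in rows) {
      out[t] <- out[t] +
        tab$p_tw[k] * sum(doc$tokens == tab$word[k]) / doc$n_words
    }
  }
  out
}

# small and mid-size simulations, cached across test files
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_sim <- function() cached("small_sim", {
  sim_corpus(swb_sim_config(n_users = 150, mean_statuses = 45, seed = 5),
             raw_text = FALSE)
})

small_sim_text <- function() cached("small_sim_text", {
  sim_corpus(swb_sim_config(n_users = 60, mean_statuses = 40, seed = 6),
             raw_text = TRUE)
})

mid_sim <- function() cached("mid_sim", {
  sim_corpus(swb_sim_config(n_users = 1000, seed = 3), raw_text = FALSE)
})

sim_outcomes <- function(sim) {
  data.frame(user_id = sim$truth$user_id, swl = sim$truth$swl_self,
             cesd = sim$truth$cesd, stringsAsFactors = FALSE)
}

# default-scale pipeline runs shared by the acceptance criteria: one
# generator + fit + validity pass per seed, reduced to small summaries
acceptance_runs <- function(seeds = 1:10) {
  cached("acceptance_runs", {
    lapply(seeds, function(sd) {
      sim <- sim_corpus(swb_sim_config(seed = sd), raw_text = FALSE)
      outc <- sim_outcomes(sim)
      fit <- swb_fit(sim$corpus, outc, sim$lexicon, sim$topic_table,
                     sim$category_lexicon, seed = sd)
      te <- fit$split$test
      lat <- sim$truth$swl_latent[match(te, sim$truth$user_id)]
      pred_te <- swbprofiler:::.forest_predict(fit$forest,
                                               fit$features[te, , drop = FALSE])
      val <- cesd_validity(fit, outc)
      planted <- paste0("topic:", sim$informative_topics)
      ev <- fit$evaluation
      list(seed = sd,
           n_users = length(fit$y),
           recovered = sum(planted %in% fit$selection$feature),
           n_planted = length(planted),
           ladder = stats::setNames(ev$r, ev$feature_set),
           r_latent = stats::cor(pred_te, lat),
           r_self = ev$r[nrow(ev)],
           validity = stats::setNames(val$r, val$feature_set),
           pred_range_ok = all(pred_te >= min(fit$y[fit$split$train]) &
                                 pred_te <= max(fit$y[fit$split$train])))
    })
  })
}
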