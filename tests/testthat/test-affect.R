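test_that("status scoring counts signed lexicon hits including repeats", {
  lex <- data.frame(word = c("love", "happyface", "bad", "good"),
                    valence = c(1, 1, -1, 1))
  expect_equal(score_status(c("love", "happyface", "rain"), lex)$valence_sum, 2)
  expect_equal(score_status(c("love", "happyface", "rain"), lex)$polarity,
               "positive")
  expect_equal(score_status(character(0), lex),
               data.frame(valence_sum = 0L, polarity = "neutral"))
  expect_equal(score_status(c("good", "bad"), lex)$polarity, "neutral")
  # repeats each count
  expect_equal(score_status(c("bad", "bad", "bad"), lex)$valence_sum, -3)
})

test_that("sentiment scorer matches the brute-force oracle on random statuses", {
  lex <- sim_valence_lexicon(40, 40, seed = 4)
  vocab <- c(lex$word, sprintf("neutral%03d", 1:60))
  set.seed(101)
  toks <- lapply(1:300, function(i)
    sample(vocab, sample(0:25, 1), replace = TRUE))
  got <- score_status(toks, lex)$valence_sum
  want <- vapply(toks, oracle_score, integer(1), lexicon = lex)
  expect_identical(got, as.integer(want))
})

test_that("user-level affect features follow the status-count normalization", {
  f <- user_affect(data.frame(valence_sum = c(2, -1, 0)))
  expect_equal(f$mean_sentiment, 1 / 3)
  expect_equal(f$pos_freq, 1 / 3)
  expect_equal(f$neg_freq, 1 / 3)
  expect_equal(f$pos_neg_ratio, 1)

  allneut <- user_affect(c(0, 0))
  expect_equal(allneut$mean_sentiment, 0)
  expect_equal(allneut$pos_freq, 0)
  expect_true(is.na(allneut$pos_neg_ratio_raw))

  # add-one smoothing when no negative status exists
  f2 <- user_affect(c(1, 1))
  expect_equal(f2$pos_neg_ratio, 3)
  expect_error(user_affect(numeric(0)), "zero statuses")
})

test_that("positive-status counts are conserved across users", {
  sim <- small_sim()
  sc <- score_status(sim$corpus$tokens, sim$lexicon)
  aff <- do.call(rbind, lapply(split(sc$valence_sum, sim$corpus$user_id),
                               user_affect))
  expect_equal(sum(aff$n_statuses * aff$pos_freq), sum(sc$valence_sum > 0))
  expect_equal(sum(aff$n_statuses * aff$neg_freq), sum(sc$valence_sum < 0))
})

test_that("flipping lexicon signs negates sentiment and swaps frequencies", {
  lex <- sim_valence_lexicon(30, 30, seed = 8)
  flipped <- transform(lex, valence = -valence)
  set.seed(42)
  toks <- lapply(1:50, function(i) sample(c(lex$word, "zzz"), 12, replace = TRUE))
  a <- user_affect(score_status(toks, lex))
  b <- user_affect(score_status(toks, flipped))
  expect_equal(a$mean_sentiment, -b$mean_sentiment)
  expect_equal(a$pos_freq, b$neg_freq)
  expect_equal(a$neg_freq, b$pos_freq)
})

test_that("affect/SWL correlation table is symmetric with unit diagonal", {
  sim <- small_sim()
  sc <- score_status(sim$corpus$tokens, sim$lexicon)
  aff <- do.call(rbind, lapply(split(sc$valence_sum, sim$corpus$user_id),
                               user_affect))
  aff$user_id <- rownames(aff)
  res <- affect_swl_correlations(aff, sim_outcomes(sim))
  expect_equal(diag(res$r), rep(1, 5), ignore_attr = TRUE)
  expect_equal(res$r, t(res$r))
  expect_gt(res$r["swl", "mean_sentiment"], 0)
  # constant column is flagged NA, not zero
  aff2 <- aff
  aff2$pos_neg_ratio <- 1
  res2 <- suppressWarnings(affect_swl_correlations(aff2, sim_outcomes(sim)))
  expect_true(is.na(res2$r["swl", "pos_neg_ratio"]))
})
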