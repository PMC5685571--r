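test_that("valence lexicon has exact counts, reserved tokens, disjoint signs", {
  lex <- sim_valence_lexicon(1, 1, seed = 0)
  expect_setequal(lex$word, c("happyface", "sadface"))
  expect_equal(lex$valence[lex$word == "happyface"], 1)
  expect_equal(lex$valence[lex$word == "sadface"], -1)

  lex2 <- sim_valence_lexicon(100, 100, seed = 1)
  expect_equal(nrow(lex2), 200)
  expect_equal(sum(lex2$valence == 1), 100)
  expect_equal(sum(lex2$valence == -1), 100)
  expect_equal(anyDuplicated(lex2$word), 0)

  expect_identical(sim_valence_lexicon(50, 30, seed = 9),
                   sim_valence_lexicon(50, 30, seed = 9))
})

test_that("topic table plants the truncation pathology", {
  tab <- sim_topic_table(40, 10, seed = 2)
  expect_true(all(tab$p_tw > 0 & tab$p_tw <= 1))
  per_topic <- table(tab$topic_id)
  expect_true(all(per_topic <= 10))
  occurrences <- table(tab$word)
  # exclusive words exist and carry p = 1
  excl <- names(occurrences)[occurrences == 1]
  expect_gt(length(excl), 0)
  expect_true(all(tab$p_tw[tab$word %in% excl] == 1))
  # shared words exist; per-word probabilities sum to at most 1
  expect_gt(sum(occurrences > 1), 0)
  sums <- tapply(tab$p_tw, tab$word, sum)
  expect_true(all(sums <= 1 + 1e-12))

  one <- sim_topic_table(1, 1, seed = 0)
  expect_equal(nrow(one), 1)
  expect_equal(one$p_tw, 1)
})

test_that("generated users pass the retention filter and carry ground truth", {
  sim <- small_sim()
  expect_true(all(sim$truth$n_statuses >= 30))
  expect_setequal(unique(sim$corpus$user_id), sim$truth$user_id)
  expect_true(all(sim$truth$swl_latent >= 1 & sim$truth$swl_latent <= 7))
  expect_true(all(sim$informative_topics %in% sim$topic_table$topic_id))
  # negative SWL / CES-D coupling by construction
  ok <- is.finite(sim$truth$cesd)
  expect_lt(cor(sim$truth$swl_latent[ok], sim$truth$cesd[ok]), 0)
})

test_that("generation fails loudly when the retention filter empties the corpus", {
  cfg <- swb_sim_config(n_users = 20, mean_statuses = 2, nb_size = 5, seed = 1)
  expect_error(sim_corpus(cfg, raw_text = FALSE), "retention")
})

test_that("identical seeds give identical corpora", {
  cfg <- swb_sim_config(n_users = 40, mean_statuses = 40, seed = 77)
  s1 <- sim_corpus(cfg, raw_text = TRUE)
  s2 <- sim_corpus(cfg, raw_text = TRUE)
  expect_identical(s1$corpus, s2$corpus)
  expect_identical(s1$truth, s2$truth)
  s3 <- sim_corpus(swb_sim_config(n_users = 40, mean_statuses = 40, seed = 78),
                   raw_text = TRUE)
  expect_false(identical(s1$corpus$text, s3$corpus$text))
})

test_that("planted affect structure appears at n = 1000: positive skew and Table-1 signs", {
  sim <- mid_sim()
  pc <- sim$corpus
  sc <- score_status(pc$tokens, sim$lexicon)
  aff <- do.call(rbind, lapply(split(sc$valence_sum, pc$user_id), user_affect))
  aff$user_id <- rownames(aff)
  m <- merge(aff, sim$truth, by = "user_id")
  # most users have more positive than negative statuses
  expect_gt(mean(m$pos_freq > m$neg_freq), 0.75)
  # correlation signs of the planted links
  expect_gt(cor(m$mean_sentiment, m$swl_latent), 0)
  expect_lt(cor(m$neg_freq, m$swl_latent), 0)
})

test_that("corpus bundle round-trips through the plain-text writers", {
  sim <- small_sim_text()
  dir <- withr::local_tempdir()
  paths <- write_swb_sim(sim, dir)
  corp <- read_corpus(paths[["statuses"]])
  expect_equal(nrow(corp), nrow(sim$corpus))
  expect_equal(corp$user_id, sim$corpus$user_id)
  expect_equal(corp$text, sim$corpus$text)
  outc <- read_outcomes(paths[["outcomes"]])
  expect_equal(nrow(outc), nrow(sim$truth))
  expect_equal(outc$swl, sim$truth$swl_self, tolerance = 1e-12)
  lex <- read_valence_lexicon(paths[["lexicon"]])
  expect_equal(lex, sim$lexicon)
  tab <- read_topic_table(paths[["topics"]])
  expect_equal(tab, sim$topic_table, tolerance = 1e-12)
})

test_that("writing an empty corpus still produces valid files", {
  dir <- withr::local_tempdir()
  empty <- data.frame(user_id = character(0), text = character(0))
  p <- file.path(dir, "empty.tsv")
  write_corpus(empty, p)
  expect_equal(nrow(read_corpus(p)), 0)
})
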