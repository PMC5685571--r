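test_that("category counts use the status-count normalization", {
  lex <- data.frame(category = c("negemo", "negemo", "motion"),
                    word = c("sad", "gloom", "run"))
  doc <- make_doc(c("sad", "sad", "run"), n_statuses = 2)
  cc <- category_counts(doc, lex)
  expect_equal(cc$count[cc$category == "negemo"], 2)
  expect_equal(cc$normalized[cc$category == "negemo"], 1)
  expect_equal(cc$count[cc$category == "motion"], 1)

  empty <- category_counts(make_doc(character(0), 3), lex)
  expect_true(all(empty$count == 0))
})

test_that("word-count scoring credits every topic containing a word", {
  tab <- data.frame(topic_id = c("winter", "winter", "kitchen", "cold", "cold"),
                    word = c("driveway", "ice", "oven", "ice", "frost"),
                    p_tw = c(1, 0.049, 1, 0.3, 0.9))
  # a word in exactly one topic credits only that topic
  s1 <- topic_wordcount_scores(make_doc("driveway"), tab)
  expect_equal(s1[["winter"]], 1)
  expect_equal(s1[["kitchen"]], 0)
  # a word in several topics credits all of them equally
  s2 <- topic_wordcount_scores(make_doc("ice"), tab)
  expect_equal(s2[["winter"]], 1)
  expect_equal(s2[["cold"]], 1)
  expect_true(all(topic_wordcount_scores(make_doc(character(0)), tab) == 0))
})

test_that("probability scoring weights by p(t|w) and word frequency", {
  tab <- data.frame(topic_id = c("winter", "winter"),
                    word = c("driveway", "ice"), p_tw = c(1, 0.049))
  expect_equal(topic_probability_scores(make_doc("driveway"), tab)[["winter"]], 1)
  d <- make_doc(c("ice", "x"))
  expect_equal(topic_probability_scores(d, tab)[["winter"]], 0.049 / 2)
  expect_error(topic_probability_scores(make_doc(character(0)), tab),
               "zero words")
})

test_that("both scorers match a naive double-loop oracle on random documents", {
  set.seed(202)
  for (i in 1:8) {
    tab <- sim_topic_table(n_topics = 10 + i, words_per_topic = 5 + i, seed = i)
    vocab <- c(unique(tab$word), sprintf("fl%02d", 1:15))
    for (j in 1:25) {
      doc <- make_doc(sample(vocab, sample(5:60, 1), replace = TRUE))
      expect_equal(topic_wordcount_scores(doc, tab), oracle_wordcount(doc, tab))
      expect_equal(topic_probability_scores(doc, tab),
                   oracle_probability(doc, tab), tolerance = 1e-12)
    }
  }
})

test_that("word-count scores are additive over document concatenation", {
  tab <- sim_topic_table(12, 6, seed = 3)
  vocab <- unique(tab$word)
  set.seed(7)
  a <- sample(vocab, 30, replace = TRUE)
  b <- sample(vocab, 40, replace = TRUE)
  expect_equal(topic_wordcount_scores(make_doc(c(a, b)), tab),
               topic_wordcount_scores(make_doc(a), tab) +
                 topic_wordcount_scores(make_doc(b), tab))
})

test_that("probability scores are scale invariant, word counts are not", {
  tab <- sim_topic_table(12, 6, seed = 4)
  set.seed(8)
  toks <- sample(unique(tab$word), 25, replace = TRUE)
  one <- make_doc(toks)
  two <- make_doc(rep(toks, 2))
  expect_equal(topic_probability_scores(two, tab),
               topic_probability_scores(one, tab), tolerance = 1e-12)
  expect_equal(topic_wordcount_scores(two, tab),
               2 * topic_wordcount_scores(one, tab))
})

test_that("with single-topic words, per-user topic probabilities sum to at most 1", {
  tab <- sim_topic_table(10, 5, seed = 5, shared_fraction = 0)
  expect_true(all(table(tab$word) == 1)) # all exclusive by construction
  set.seed(9)
  doc <- make_doc(sample(c(unique(tab$word), "pad"), 40, replace = TRUE))
  expect_lte(sum(topic_probability_scores(doc, tab)), 1 + 1e-12)
})

test_that("scoring-ratio comparison reports both spreads with its edge cases", {
  tab <- data.frame(topic_id = c("a", "b"), word = c("wa", "wb"),
                    p_tw = c(0.5, 0.5))
  r <- compare_scoring_ratio(make_doc(c("wa", "wb")), tab)
  expect_equal(unname(r), c(1, 1))
  # dominant p = 1 word versus minor low-p word inflates only the probability spread
  tab2 <- data.frame(topic_id = c("a", "b"), word = c("wa", "wb"),
                     p_tw = c(1, 0.05))
  r2 <- compare_scoring_ratio(make_doc(c("wa", "wb")), tab2)
  expect_equal(r2[["ratio_wordcount"]], 1)
  expect_gt(r2[["ratio_probability"]], r2[["ratio_wordcount"]])
  expect_error(compare_scoring_ratio(make_doc("wa"), tab), "fewer than 2")
})

test_that("assembled feature matrix matches the per-document operations", {
  sim <- small_sim()
  fm <- build_feature_matrix(sim$corpus, sim$lexicon, sim$topic_table,
                             sim$category_lexicon)
  X <- fm$X
  expect_false(anyNA(X))
  expect_equal(anyDuplicated(colnames(X)), 0)
  expect_equal(rownames(X), sort(unique(sim$corpus$user_id)))
  expect_true(all(grepl("^(affect|cat|topic):", colnames(X))))

  docs <- user_documents(sim$corpus)
  for (u in sample(names(docs), 5)) {
    doc <- docs[[u]]
    wc <- topic_wordcount_scores(doc, sim$topic_table) / doc$n_statuses
    expect_equal(unname(X[u, paste0("topic:", names(wc))]), unname(wc),
                 tolerance = 1e-12)
    cc <- category_counts(doc, sim$category_lexicon)
    expect_equal(unname(X[u, paste0("cat:", cc$category)]), cc$normalized,
                 tolerance = 1e-12)
  }
})
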