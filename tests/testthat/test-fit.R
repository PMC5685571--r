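# small-scale checks of the fitting surface; statistical performance at the
# default study scale is exercised in test-acceptance.R

fit_small <- function() cached("fit_small", {
  sim <- small_sim()
  swb_fit(sim$corpus, sim_outcomes(sim), sim$lexicon, sim$topic_table,
          sim$category_lexicon, seed = 42, ntree = 200)
})

test_that("the fitted object exposes the modelling surface coherently", {
  sim <- small_sim()
  fit <- fit_small()
  expect_s3_class(fit, "swb_fit")
  expect_equal(fit$evaluation$feature_set[1], "baseline")
  expect_true(all(c("selected topics + sentiment",
                    "selected topics + categories + sentiment") %in%
                    fit$evaluation$feature_set))
  # coef returns the elastic-net selection
  expect_equal(unname(coef(fit)), fit$selection$coefficient)
  # fitted/residuals are OOB-based and aligned
  expect_equal(names(fitted(fit)), names(fit$y))
  expect_equal(residuals(fit), fit$y - fitted(fit))
  expect_output(print(fit), "Satisfaction-with-life model")
  expect_output(summary(fit), "Feature-set ladder")
})

test_that("predictions respect the training response range and user alignment", {
  fit <- fit_small()
  te <- fit$split$test
  pred <- predict(fit, fit$features[te, , drop = FALSE])
  expect_equal(names(pred), te)
  tr_rng <- range(fit$y[fit$split$train])
  expect_true(all(pred >= tr_rng[1] & pred <= tr_rng[2]))
  expect_error(
    predict(fit, fit$features[te, "affect:pos_neg_ratio", drop = FALSE]),
    "lacks feature")
})

test_that("predicting from a raw corpus reruns the full feature pipeline", {
  sim <- small_sim_text()
  outc <- sim_outcomes(sim)
  fit <- swb_fit(sim$corpus, outc, sim$lexicon, sim$topic_table,
                 sim$category_lexicon, seed = 7, ntree = 150)
  pred <- predict(fit, sim$corpus, lexicon = sim$lexicon,
                  topic_table = sim$topic_table,
                  category_lexicon = sim$category_lexicon)
  expect_length(pred, length(fit$y))
  expect_gt(cor(pred[names(fit$y)], fit$y), 0) # in-sample, loose sanity
})

test_that("refitting with the same seed reproduces the model exactly", {
  sim <- small_sim()
  f1 <- fit_small()
  f2 <- swb_fit(sim$corpus, sim_outcomes(sim), sim$lexicon, sim$topic_table,
                sim$category_lexicon, seed = 42, ntree = 200)
  expect_identical(f1$evaluation, f2$evaluation)
  expect_identical(f1$oob_swl, f2$oob_swl)
})

test_that("the SWB profile bundles predicted SWL with the three sentiment features", {
  fit <- fit_small()
  prof <- swb_profile(fit)
  expect_equal(ncol(prof), 5) # user_id + 4 profile fields
  expect_setequal(setdiff(names(prof), "user_id"),
                  c("predicted_swl", "mean_sentiment", "pos_freq", "neg_freq"))
  expect_setequal(prof$user_id, names(fit$oob_swl))
  # round-trip through CSV preserves values
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(prof, p, row.names = FALSE)
  back <- utils::read.csv(p, colClasses = c(user_id = "character"))
  expect_equal(back$predicted_swl, prof$predicted_swl, tolerance = 1e-12)
})

test_that("profile correlations with CES-D carry the planted negative sign", {
  sim <- small_sim()
  fit <- fit_small()
  cc <- criterion_correlations(swb_profile(fit), sim_outcomes(sim))
  expect_lt(cc$r[cc$field == "predicted_swl"], 0)
  # CES-D correlated with itself is 1
  prof2 <- merge(swb_profile(fit), sim_outcomes(sim), by = "user_id")
  prof2 <- data.frame(user_id = prof2$user_id, cesd_copy = prof2$cesd)
  cc2 <- criterion_correlations(prof2, sim_outcomes(sim))
  expect_equal(cc2$r[cc2$field == "cesd_copy"], 1)
})

test_that("CES-D validity rows share one split and include the baseline", {
  sim <- small_sim()
  fit <- fit_small()
  v <- cesd_validity(fit, sim_outcomes(sim), min_users = 10)
  expect_equal(v$feature_set,
               c("baseline", "sentiment", "self-reported SWL + sentiment",
                 "machine-predicted SWL + sentiment"))
  expect_equal(v$n_features, c(1L, 3L, 4L, 4L))
  expect_equal(length(unique(v$n)), 1) # identical test set for every row
  n_cesd <- sum(is.finite(sim$truth$cesd))
  expect_equal(attr(v, "n_train") + attr(v, "n_test"), n_cesd)
  expect_equal(attr(v, "n_train"), round(0.7 * n_cesd))
  expect_error(cesd_validity(fit, sim_outcomes(sim), min_users = 1e6),
               "CES-D")
})

test_that("grid search inside the fit honors a custom grid", {
  sim <- small_sim()
  fit <- swb_fit(sim$corpus, sim_outcomes(sim), sim$lexicon, sim$topic_table,
                 sim$category_lexicon, seed = 3,
                 grid = data.frame(ntree = c(100, 200), mtry = c(2, 2)))
  expect_false(is.null(fit$grid_results))
  expect_equal(nrow(fit$grid_results), 2)
  expect_true(fit$config$ntree %in% c(100, 200))
})
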