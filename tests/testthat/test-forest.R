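test_that("forest fit is deterministic, bounded, and degenerate-safe", {
  set.seed(31)
  n <- 200
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- X[, 1] + rnorm(n, 0, 0.3)
  f1 <- fit_forest(X, y, ntree = 200, mtry = 2, seed = 7)
  f2 <- fit_forest(X, y, ntree = 200, mtry = 2, seed = 7)
  expect_identical(f1$oob, f2$oob)
  pred <- swbprofiler:::.forest_predict(f1, X)
  expect_true(all(pred >= min(y) & pred <= max(y)))
  # constant response: every prediction equals it
  fc <- fit_forest(X, rep(3, n), ntree = 50, mtry = 2, seed = 1)
  expect_true(all(abs(fc$oob - 3) < 1e-12))
  expect_error(fit_forest(X[1, , drop = FALSE], 1), "at least 2")
})

test_that("grid search scores by OOB correlation and breaks ties to smaller cells", {
  set.seed(32)
  n <- 120
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- X[, 1] + rnorm(n, 0, 0.5)
  one <- grid_search(X, y, grid = data.frame(ntree = 300, mtry = 2), seed = 1)
  expect_equal(one$best$ntree, 300)
  expect_equal(nrow(default_forest_grid()), 8)
  # degenerate response: all cells tie with undefined r; smallest cell wins
  gs <- suppressWarnings(grid_search(X, rep(1, n),
                                     grid = default_forest_grid(), seed = 1))
  expect_equal(gs$best$ntree, 500)
  expect_equal(gs$best$mtry, 2)
})

test_that("evaluation reports exact correlation and RMSE", {
  ev <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ev$r, 1)
  expect_equal(ev$rmse, 0)
  ev2 <- evaluate_predictions(c(2, 3, 4), c(1, 2, 3))
  expect_equal(ev2$r, 1)
  expect_equal(ev2$rmse, 1)
  ev3 <- evaluate_predictions(c(1, 2, 3), c(2, 4, 6))
  expect_equal(ev3$r, 1)
  expect_equal(ev3$rmse, sqrt(14 / 3))
  expect_true(is.na(suppressWarnings(
    evaluate_predictions(c(1, 1, 1), c(1, 2, 3))$r)))
  expect_error(evaluate_predictions(1:3, 1:4), "lengths differ")
})

test_that("evaluator matches closed-form Pearson and RMSE on random pairs", {
  set.seed(33)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    a <- rnorm(n); b <- 0.5 * a + rnorm(n)
    ev <- evaluate_predictions(a, b)
    r_manual <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    t_manual <- r_manual * sqrt((n - 2) / (1 - r_manual^2))
    expect_equal(ev$r, r_manual, tolerance = 1e-10)
    expect_equal(ev$p, 2 * stats::pt(-abs(t_manual), n - 2), tolerance = 1e-10)
    expect_equal(ev$rmse, sqrt(mean((a - b)^2)), tolerance = 1e-10)
  }
})

test_that("jittered-median baseline stays in its band and carries no signal", {
  y <- c(3, 4, 5, 6, 10)
  b <- baseline_predict(y, 500, seed = 2)
  expect_true(all(b >= 5 & b <= 5.001))
  expect_identical(baseline_predict(y, 10, seed = 3),
                   baseline_predict(y, 10, seed = 3))
  expect_error(baseline_predict(numeric(0), 5), "empty")
})

test_that("permutation importance ranks the planted predictor first", {
  set.seed(34)
  n <- 400
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, c("signal", sprintf("noise%d", 1:5))))
  y <- 2 * X[, "signal"] + rnorm(n, 0, 0.5)
  f <- fit_forest(X[1:300, ], y[1:300], ntree = 300, mtry = 2, seed = 5)
  imp <- variable_importance(f, X[301:400, ], y[301:400], seed = 6)
  expect_equal(imp$feature[1], "signal")
  # noise features sit near zero relative to the signal
  expect_true(all(imp$importance[imp$feature != "signal"] <
                    0.2 * imp$importance[1]))
  expect_identical(variable_importance(f, X[301:400, ], y[301:400], seed = 6),
                   imp)
})

test_that("forest agrees with an independent bagging implementation", {
  set.seed(35)
  n <- 250
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- X[, 1] - X[, 2] + rnorm(n, 0, 0.4)
  ours <- fit_forest(X, y, ntree = 500, mtry = 2, seed = 1)
  rf <- randomForest::randomForest(X, y, ntree = 500, mtry = 2)
  expect_gt(cor(ours$oob, rf$predicted), 0.9)
})

test_that("simulated OOB fraction matches the bootstrap expectation", {
  res <- oob_fraction_sim(1873, rounds = 200, seed = 1)
  expect_equal(res$expected, (1 - 1 / 1873)^1873)
  expect_lt(abs(res$mean_oob_fraction - res$expected), 0.005)
})
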