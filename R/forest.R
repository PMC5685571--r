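#' Fit the random-forest SWL regression
#'
#' Bootstrap-aggregated regression trees: each tree is grown on a bootstrap
#' resample of the training users, predictions are the mean over trees, and
#' each user's out-of-bag (OOB) prediction averages only the trees whose
#' bootstrap sample excluded that user — an internal validation estimate that
#' costs no held-out data. On average about 37% of training instances are
#' out-of-bag in each round (the (1 - 1/n)^n limit; see [oob_fraction_sim()]).
#'
#' @param X numeric feature matrix (named columns).
#' @param y numeric response aligned with rows of `X`.
#' @param ntree number of trees (default 1000).
#' @param mtry candidate features per split (default 3).
#' @param seed seed (fits are deterministic given it).
#' @return list of class `swb_forest`: `model` (ranger fit), `oob`
#'   (per-row OOB predictions), `ntree`, `mtry`, `seed`, `y_range`.
#' @export
fit_forest <- function(X, y, ntree = 1000, mtry = 3, seed = 1) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (nrow(X) < 2L) .fail("need at least 2 samples to fit a forest")
  mtry <- min(mtry, ncol(X))
  fit <- ranger::ranger(x = X, y = y, num.trees = ntree, mtry = mtry,
                        seed = stage_seed(seed, 31), num.threads = 1,
                        oob.error = TRUE, respect.unordered.factors = "order")
  structure(list(model = fit, oob = fit$predictions, ntree = ntree,
                 mtry = mtry, seed = seed, y_range = range(y),
                 features = colnames(X)),
            class = "swb_forest")
}

#' @export
print.swb_forest <- function(x, ...) {
  cat(sprintf("Random forest: %d trees, mtry = %d, %d features; OOB MSE = %.4f\n",
              x$ntree, x$mtry, length(x$features), x$model$prediction.error))
  invisible(x)
}

# predict for a swb_forest on a feature matrix (columns matched by name)
.forest_predict <- function(forest, X) {
  miss <- setdiff(forest$features, colnames(X))
  if (length(miss))
    .fail("newdata lacks feature(s): %s", paste(utils::head(miss, 5), collapse = ", "))
  stats::predict(forest$model, data = X[, forest$features, drop = FALSE],
                 num.threads = 1)$predictions
}

#' Manual grid search over forest hyperparameters
#'
#' Fits one forest per (ntree, mtry) cell and scores each by the Pearson
#' correlation between its OOB predictions and the response. Ties are broken
#' toward the smaller ntree, then the smaller mtry. The default grid is the
#' eight-cell ntree {500, 1000, 1500, 2000} x mtry {2, 3}.
#'
#' @inheritParams fit_forest
#' @param grid data frame with columns `ntree` and `mtry`.
#' @return list: `best` (the winning `swb_forest`), `results` (data frame
#'   `ntree`, `mtry`, `oob_r`).
#' @export
grid_search <- function(X, y, grid = default_forest_grid(), seed = 1) {
  stopifnot(nrow(grid) >= 1, all(c("ntree", "mtry") %in% names(grid)))
  res <- grid
  res$oob_r <- NA_real_
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- fit_forest(X, y, ntree = grid$ntree[i], mtry = grid$mtry[i],
                            seed = seed)
    r <- suppressWarnings(.cor_test(fits[[i]]$oob, y)$r)
    res$oob_r[i] <- if (is.na(r)) -Inf else r
  }
  ord <- order(-res$oob_r, res$ntree, res$mtry)
  best <- ord[1]
  res$oob_r[!is.finite(res$oob_r)] <- NA_real_
  list(best = fits[[best]], results = res)
}

#' @rdname grid_search
#' @export
default_forest_grid <- function() {
  expand.grid(ntree = c(500, 1000, 1500, 2000), mtry = c(2, 3))
}

#' Evaluate predictions against self-reports
#'
#' Pearson correlation with a two-sided p-value, plus the root mean square
#' error, on paired complete cases. A constant vector makes the correlation
#' undefined and is flagged as `NA` rather than silently reported as zero.
#'
#' @param pred,truth numeric vectors of equal length (>= 3).
#' @return one-row data frame: `r`, `p`, `rmse`, `n`.
#' @export
#' @examples
#' evaluate_predictions(c(1, 2, 3), c(2, 4, 6))
evaluate_predictions <- function(pred, truth) {
  if (length(pred) != length(truth)) .fail("pred and truth lengths differ")
  if (length(pred) < 3L) .fail("need at least 3 pairs to evaluate")
  ok <- is.finite(pred) & is.finite(truth)
  ct <- .cor_test(pred[ok], truth[ok])
  data.frame(r = ct$r, p = ct$p, rmse = .rmse(pred[ok], truth[ok]),
             n = sum(ok))
}

#' Jittered-median baseline predictor
#'
#' The naive reference model: every test user is predicted the median of the
#' training SWL scores, plus an i.i.d. U(0, 0.001) jitter so that a
#' correlation with the target is computable at all. Its correlation with any
#' independent target is near zero by construction.
#'
#' @param y_train training responses (nonempty).
#' @param n_test number of predictions to produce.
#' @param seed seed.
#' @return numeric vector of length `n_test` in
#'   \[median(y_train), median(y_train) + 0.001\].
#' @export
baseline_predict <- function(y_train, n_test, seed = 1) {
  if (!length(y_train)) .fail("y_train is empty")
  set.seed(stage_seed(seed, 32))
  stats::median(y_train) + stats::runif(n_test, 0, 0.001)
}

#' Permutation variable importance
#'
#' Mean increase in squared prediction error on evaluation data after
#' permuting one feature column at a time (averaged over `repeats`
#' permutations), the "mean decrease in accuracy" principle for regression
#' forests. Plain permutation importance is computed on the supplied
#' evaluation set; no conditional (correlation-adjusted) variant is offered.
#'
#' @param forest a fitted `swb_forest`.
#' @param X evaluation feature matrix (held-out rows, or training rows for an
#'   OOB-flavoured estimate).
#' @param y evaluation response.
#' @param repeats permutations per feature (default 5).
#' @param seed seed (ranking is deterministic given it).
#' @return data frame (`feature`, `importance`) in descending importance.
#' @export
variable_importance <- function(forest, X, y, repeats = 5, seed = 1) {
  stopifnot(inherits(forest, "swb_forest"))
  X <- X[, forest$features, drop = FALSE]
  base_mse <- mean((.forest_predict(forest, X) - y)^2)
  set.seed(stage_seed(seed, 33))
  imp <- vapply(seq_len(ncol(X)), function(j) {
    d <- numeric(repeats)
    for (k in seq_len(repeats)) {
      Xp <- X
      Xp[, j] <- Xp[sample.int(nrow(X)), j]
      d[k] <- mean((.forest_predict(forest, Xp) - y)^2) - base_mse
    }
    mean(d)
  }, numeric(1))
  out <- data.frame(feature = colnames(X), importance = imp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate the out-of-bag fraction of bootstrap resampling
#'
#' Draws `rounds` bootstrap resamples of size `n` and measures the fraction
#' of the n instances absent from each resample. The expectation is
#' (1 - 1/n)^n, about 36.8% for large n — the familiar "about 37%
#' out-of-bag" property of bagged ensembles.
#'
#' @param n sample size (e.g. the number of training users).
#' @param rounds bootstrap rounds (default 1000).
#' @param seed seed.
#' @return list: `mean_oob_fraction`, `expected` ((1-1/n)^n), `per_round`.
#' @export
#' @examples
#' oob_fraction_sim(100, rounds = 50, seed = 1)$mean_oob_fraction
oob_fraction_sim <- function(n, rounds = 1000, seed = 1) {
  stopifnot(n >= 1, rounds >= 1)
  set.seed(stage_seed(seed, 34))
  frac <- vapply(seq_len(rounds), function(i) {
    1 - length(unique(sample.int(n, n, replace = TRUE))) / n
  }, numeric(1))
  list(mean_oob_fraction = mean(frac), expected = (1 - 1 / n)^n,
       per_round = frac)
}
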