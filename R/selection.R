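#' Deterministic train/test split of users
#'
#' @param users character vector of user ids.
#' @param train_fraction fraction in (0, 1); the training set has
#'   `round(train_fraction * n)` users.
#' @param seed split seed.
#' @return list with `train` and `test` id vectors (disjoint, union = users).
#' @export
#' @examples
#' split_train_test(sprintf("u%02d", 1:10), 0.5, seed = 1)
split_train_test <- function(users, train_fraction, seed = 1) {
  n <- length(users)
  if (n < 2L) .fail("need at least 2 users to split")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    .fail("train_fraction must lie strictly between 0 and 1")
  set.seed(stage_seed(seed, 21))
  n_train <- round(train_fraction * n)
  tr <- sort(sample(users, n_train))
  list(train = tr, test = sort(setdiff(users, tr)))
}

#' Elastic-net feature reduction
#'
#' Penalized linear regression of SWL on the category/topic features,
#' combining ridge and lasso penalties, fitted on the training partition
#' only. Features are standardized internally (train statistics); the penalty
#' strength lambda is chosen by 10-fold cross-validation on the training data
#' at the 1-SE rule. Features with nonzero coefficients at that lambda are
#' the selected set. A small mixing value (default 0.1, mostly ridge) keeps
#' groups of correlated informative features in the model rather than
#' arbitrarily keeping one representative, and minimizes sparsity of the
#' result.
#'
#' @param X numeric feature matrix (training rows only; named columns).
#' @param y numeric response (SWL), aligned with `X` rows.
#' @param mixing elastic-net mixing parameter in \[0, 1\]
#'   (0 = ridge, 1 = lasso); default 0.1.
#' @param seed seed controlling the cross-validation folds.
#' @param nfolds CV folds (default 10).
#' @param lambda_rule `"lambda.1se"` (default) or `"lambda.min"`.
#' @return object of class `swb_selection`: data frame (`feature`,
#'   `coefficient`, nonzero) with attributes `mixing`, `lambda`, `seed`,
#'   `n_candidates`.
#' @export
elastic_net_select <- function(X, y, mixing = 0.1, seed = 1, nfolds = 10,
                               lambda_rule = c("lambda.1se", "lambda.min")) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (nrow(X) < 10L) .fail("need at least 10 training users for selection")
  if (stats::sd(y) == 0) .fail("response is constant; nothing to select on")
  set.seed(stage_seed(seed, 22))
  nfolds <- max(3L, min(nfolds, nrow(X) %/% 4L)) # keep >= 4 obs per fold
  foldid <- sample(rep_len(seq_len(nfolds), nrow(X)))
  cv <- glmnet::cv.glmnet(X, y, alpha = mixing, foldid = foldid,
                          standardize = TRUE, family = "gaussian")
  lam <- cv[[lambda_rule]]
  co <- as.matrix(stats::coef(cv, s = lam))[-1, 1] # drop intercept
  sel <- co[co != 0]
  out <- data.frame(feature = names(sel), coefficient = unname(sel),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$coefficient)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mixing") <- mixing
  attr(out, "lambda") <- lam
  attr(out, "seed") <- seed
  attr(out, "n_candidates") <- ncol(X)
  class(out) <- c("swb_selection", "data.frame")
  out
}

#' @export
print.swb_selection <- function(x, ...) {
  cat(sprintf("Elastic-net selection: %d of %d features kept (mixing = %g, lambda = %.4g)\n",
              nrow(x), attr(x, "n_candidates"), attr(x, "mixing"),
              attr(x, "lambda")))
  print.data.frame(utils::head(x, 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}
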