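#' Derive a stage seed from a master seed
#'
#' One master seed fans out deterministically to per-stage seeds so that any
#' stage can be rerun in isolation and still match a full pipeline run. The
#' scheme is a fixed affine step kept below 2^31 - 1.
#'
#' @param seed master seed (integer).
#' @param stage stage counter (non-negative integer).
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  as.integer((abs(as.numeric(seed)) * 48271 + 7919 * (stage + 1)) %% 2147483647)
}

# internal: stop with a consistent prefix
.fail <- function(...) stop(sprintf(...), call. = FALSE)

.check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    .fail("%s is missing column(s): %s", what, paste(miss, collapse = ", "))
  invisible(df)
}

# Pearson r with two-sided p; constant input yields NA r (flagged), never 0.
.cor_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(list(r = NA_real_, p = NA_real_, n = n))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined for a constant vector; returning NA")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

.rmse <- function(pred, truth) sqrt(mean((pred - truth)^2))
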