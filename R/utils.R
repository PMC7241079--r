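## Internal helpers shared across modules.

## Derive a reproducible 32-bit sub-seed from a base seed and a stage name so
## each pipeline stage consumes an independent stream.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

## Column-standardize a matrix (center, scale by n-1 SD). Columns with zero
## variance raise an error naming the offender unless zero_ok, in which case
## they become all-zero.
standardize_columns <- function(X, zero_ok = FALSE) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  zero <- sdv < .Machine$double.eps^0.5
  if (any(zero) && !zero_ok) {
    nm <- colnames(X)[zero]
    if (is.null(nm)) nm <- which(zero)
    stop("zero-variance column(s): ", paste(nm, collapse = ", "))
  }
  sdv[zero] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  Xs[, zero] <- 0
  Xs
}

## Pearson correlation p-value via the t transform, two-sided.
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  df <- n - 2
  t <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), df)
  p[abs(r) >= 1] <- 0
  pmin(p, 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
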