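## Shared fixture builders. Everything is generated in code; no stored data.

## Column-standardize with the n-1 denominator (local copy so tests do not
## depend on package internals).
std_cols <- function(M) {
  mu <- colMeans(M)
  sv <- apply(M, 2, sd)
  sv[sv == 0] <- 1
  sweep(sweep(M, 2, mu, "-"), 2, sv, "/")
}

## Small standardized two-block dataset with a shared latent factor on the
## leading features of each block.
make_latent_blocks <- function(n = 80, p1 = 8, p2 = 8, k1 = 3, k2 = 3,
                               noise = 0.5, seed = 11) {
  set.seed(seed)
  z <- rnorm(n)
  X1 <- matrix(rnorm(n * p1, sd = noise), n, p1)
  X2 <- matrix(rnorm(n * p2, sd = noise), n, p2)
  X1[, seq_len(k1)] <- X1[, seq_len(k1)] + z
  X2[, seq_len(k2)] <- X2[, seq_len(k2)] + z
  y <- z + rnorm(n, sd = noise)
  list(X1 = std_cols(X1), X2 = std_cols(X2),
       y = as.numeric(scale(y)), z = z, k1 = k1, k2 = k2)
}

## Hand-built similarity_matrix object with prescribed edge weights.
## `edges` is a data.frame(from, to, w); kinds alternate protein/metabolite
## unless given.
make_sim <- function(p, edges, kind = NULL) {
  A <- matrix(0, p, p)
  for (i in seq_len(nrow(edges))) {
    A[edges$from[i], edges$to[i]] <- edges$w[i]
    A[edges$to[i], edges$from[i]] <- edges$w[i]
  }
  ids <- paste0("f", seq_len(p))
  dimnames(A) <- list(ids, ids)
  if (is.null(kind))
    kind <- rep(c("protein", "metabolite"), length.out = p)
  structure(list(values = A, signs = matrix(1, p, p), feature_ids = ids,
                 feature_kind = kind, p1 = sum(kind == "protein"),
                 p2 = sum(kind == "metabolite")),
            class = "similarity_matrix")
}

## Independent maximizer of w'v over {||w||_2 <= 1, ||w||_1 <= c}: dense
## scan over soft-thresholds, refined locally. Deliberately avoids
## project_l1_l2's bisection.
oracle_l1_l2 <- function(v, c, n_grid = 4000) {
  best <- NULL
  best_val <- -Inf
  for (d in seq(0, max(abs(v)), length.out = n_grid)) {
    w <- sign(v) * pmax(abs(v) - d, 0)
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) next
    w <- w / nrm
    if (sum(abs(w)) <= c + 1e-9 && sum(w * v) > best_val) {
      best_val <- sum(w * v)
      best <- w
    }
  }
  if (is.null(best)) {       # only the one-hot corner is feasible
    i <- which.max(abs(v))
    best <- numeric(length(v))
    best[i] <- sign(v[i])
    best_val <- sum(best * v)
  }
  list(w = best, value = best_val)
}

## Independent maximizer of the weighted canonical objective with the L1
## constraint inactive (l = 1): random-restart quasi-Newton over the two
## unit spheres, independent of fit_smcca's coordinate updates.
oracle_smcca_unconstrained <- function(X1, X2, y, s, restarts = 30,
                                       seed = 99) {
  n <- nrow(X1)
  S12 <- crossprod(X1, X2) / (n - 1)
  a <- drop(crossprod(X1, y)) / (n - 1)
  b <- drop(crossprod(X2, y)) / (n - 1)
  p1 <- ncol(X1); p2 <- ncol(X2)
  negJ <- function(par) {
    w1 <- par[seq_len(p1)]; w2 <- par[p1 + seq_len(p2)]
    n1 <- sqrt(sum(w1^2)); n2 <- sqrt(sum(w2^2))
    if (n1 == 0 || n2 == 0) return(0)
    w1 <- w1 / n1; w2 <- w2 / n2
    -(drop(t(w1) %*% S12 %*% w2) + s * (sum(w1 * a) + sum(w2 * b)))
  }
  set.seed(seed)
  best <- Inf
  for (r in seq_len(restarts)) {
    par0 <- rnorm(p1 + p2)
    fit <- optim(par0, negJ, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    if (fit$value < best) best <- fit$value
  }
  -best
}

## Closed-form one-sided hypergeometric tail for a 2x2 table
## (a = in-both, b = adjusted-only, c = unadjusted-only, d = neither):
## P(overlap >= a) by direct summation of binomial coefficients.
oracle_fisher_greater <- function(a, b, c, d) {
  N <- a + b + c + d
  m <- a + b          # size of set 1
  k <- a + c          # size of set 2
  total <- choose(N, k)
  hi <- min(m, k)
  sum(vapply(a:hi, function(x)
    choose(m, x) * choose(N - m, k - x), numeric(1))) / total
}
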