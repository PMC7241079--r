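test_that("correlation range report matches an exhaustive pairwise oracle", {
  set.seed(20)
  X1 <- std_cols(matrix(rnorm(60 * 5), 60, 5))
  X2 <- std_cols(matrix(rnorm(60 * 5), 60, 5))
  y <- rnorm(60)
  rep <- correlation_range_report(X1, X2, y)
  all12 <- as.vector(outer(seq_len(5), seq_len(5),
                           Vectorize(function(i, j) cor(X1[, i], X2[, j]))))
  expect_equal(unname(rep$omics_omics), range(all12))
  r1y <- vapply(seq_len(5), function(i) cor(X1[, i], y), numeric(1))
  r2y <- vapply(seq_len(5), function(i) cor(X2[, i], y), numeric(1))
  expect_equal(unname(rep$omics_phenotype), range(c(r1y, r2y)))

  rep2 <- correlation_range_report(X1, X1, y)
  expect_equal(unname(rep2$omics_omics["max"]), 1)
  expect_error(correlation_range_report(X1[1:2, ], X2[1:2, ], y[1:2]),
               "at least 3")
})

test_that("L1/L2 projection: inactive constraint, corner case, errors", {
  v <- c(3, -1, 0.5)
  w <- project_l1_l2(v, 3)         # ||v/||v||||_1 = 4.5/3.20 = 1.40 < 3
  expect_equal(w, v / sqrt(sum(v^2)))

  ## c = 1: one-hot at the largest |v|, ties to the lowest index
  expect_equal(project_l1_l2(c(1, -2, 2, 0.3), 1), c(0, -1, 0, 0))
  expect_equal(project_l1_l2(c(0.5, 0.1), 1), c(1, 0))

  expect_error(project_l1_l2(c(1, 2), 0.9), ">= 1")
  z <- project_l1_l2(c(0, 0, 0), 2)
  expect_true(all(z == 0) && isTRUE(attr(z, "zero")))
})

test_that("L1/L2 projection beats or ties an independent threshold scan", {
  set.seed(21)
  worst <- 0
  for (rep in 1:60) {
    p <- sample(5:15, 1)
    v <- rnorm(p)
    c <- runif(1, 1, sqrt(p))
    w <- project_l1_l2(v, c)
    expect_lte(sum(abs(w)), c + 1e-6)
    expect_lte(sum(w^2), 1 + 1e-8)
    orc <- oracle_l1_l2(v, c)
    worst <- max(worst, orc$value - sum(w * v))
  }
  expect_lt(worst, 1e-4)
})

test_that("weighted objective reduces to pairwise correlations for one-hots", {
  d <- make_latent_blocks(n = 50, p1 = 4, p2 = 4, seed = 22)
  w1 <- c(1, 0, 0, 0); w2 <- c(0, 0, 1, 0)
  s <- 3
  J <- weighted_objective(w1, w2, d$X1, d$X2, d$y, s)
  expect_equal(J, cor(d$X1[, 1], d$X2[, 3]) +
                 s * (cor(d$X1[, 1], d$y) + cor(d$X2[, 3], d$y)),
               tolerance = 1e-10)
  expect_error(weighted_objective(w1, w2[-1], d$X1, d$X2, d$y, s),
               "misaligned")
})

test_that("weighted objective matches a hand dataset", {
  X1 <- std_cols(cbind(c(1, 2, 3, 4, 5, 6), c(2, 1, 4, 3, 6, 5)))
  X2 <- std_cols(cbind(c(6, 5, 4, 3, 2, 1), c(1, 3, 2, 5, 4, 6)))
  y <- as.numeric(scale(c(1, 2, 2, 3, 5, 8)))
  w1 <- c(0.6, 0.8); w2 <- c(-0.8, 0.6)
  S12 <- crossprod(X1, X2) / 5
  expected <- drop(t(w1) %*% S12 %*% w2) +
    2 * (sum(w1 * crossprod(X1, y) / 5) + sum(w2 * crossprod(X2, y) / 5))
  expect_equal(weighted_objective(w1, w2, X1, X2, y, 2), expected)
})

test_that("scalar blocks reduce to sign enumeration", {
  set.seed(23)
  x1 <- as.numeric(scale(rnorm(30)))
  x2 <- as.numeric(scale(rnorm(30) + 0.5 * x1))
  y <- as.numeric(scale(rnorm(30) - x1))
  s <- 2
  fit <- fit_smcca(cbind(x1), cbind(x2), y, s = s, l1 = 1, l2 = 1)
  Jbest <- max(vapply(list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)),
                      function(sg) weighted_objective(sg[1], sg[2],
                                                      cbind(x1), cbind(x2),
                                                      y, s),
                      numeric(1)))
  expect_equal(fit$objective_value, Jbest, tolerance = 1e-10)
  expect_true(fit$w1 %in% c(-1, 1) && fit$w2 %in% c(-1, 1))
})

test_that("unpenalized whitened fit recovers the leading singular value", {
  set.seed(24)
  n <- 150; p <- 5
  X1 <- matrix(rnorm(n * p), n, p)
  X2 <- matrix(rnorm(n * p), n, p)
  X2[, 2] <- X2[, 2] + 1.5 * X1[, 3]
  W1 <- std_cols(X1 %*% solve(chol(cov(X1))))
  W2 <- std_cols(X2 %*% solve(chol(cov(X2))))
  fit <- fit_smcca(W1, W2, rnorm(n), s = 0, l1 = 1, l2 = 1)
  sv <- svd(crossprod(W1, W2) / (n - 1))
  expect_lt(abs(fit$objective_value - sv$d[1]), 1e-6)
  ## weights align with the leading singular vectors (up to joint sign)
  expect_gt(abs(sum(fit$w1 * sv$u[, 1])), 1 - 1e-4)
  expect_gt(abs(sum(fit$w2 * sv$v[, 1])), 1 - 1e-4)
})

test_that("small instances match an independent multi-start maximizer", {
  for (seed in c(31, 32, 33)) {
    set.seed(seed)
    X1 <- std_cols(matrix(rnorm(20 * 3), 20, 3))
    X2 <- std_cols(matrix(rnorm(20 * 3), 20, 3))
    y <- as.numeric(scale(rnorm(20) + X1[, 1]))
    s <- 1.5
    fit <- fit_smcca(X1, X2, y, s = s, l1 = 1, l2 = 1)
    Jstar <- oracle_smcca_unconstrained(X1, X2, y, s, seed = seed + 100)
    expect_lt(abs(fit$objective_value - Jstar), 1e-3)
  }
})

test_that("the objective trace is monotone non-decreasing", {
  d <- make_latent_blocks(n = 100, p1 = 12, p2 = 12, seed = 25)
  for (l in c(0.25, 0.45, 1)) {
    fit <- fit_smcca(d$X1, d$X2, d$y, s = 5, l1 = l, l2 = l)
    expect_true(all(diff(fit$objective_trace) >= -1e-10))
    expect_true(fit$converged)
  }
})

test_that("fitted weights obey the norm constraints", {
  d <- make_latent_blocks(n = 80, p1 = 10, p2 = 14, seed = 26)
  for (l in c(0.35, 0.55)) {
    fit <- fit_smcca(d$X1, d$X2, d$y, s = 8, l1 = l, l2 = l)
    expect_lte(sum(fit$w1^2), 1 + 1e-8)
    expect_lte(sum(fit$w2^2), 1 + 1e-8)
    expect_lte(sum(abs(fit$w1)), max(1, l * sqrt(10)) + 1e-6)
    expect_lte(sum(abs(fit$w2)), max(1, l * sqrt(14)) + 1e-6)
  }
})

test_that("weights are invariant to positive phenotype rescaling", {
  d <- make_latent_blocks(seed = 27)
  f1 <- fit_smcca(d$X1, d$X2, as.numeric(scale(d$y)), s = 5, l1 = 0.5, l2 = 0.5)
  f2 <- fit_smcca(d$X1, d$X2, as.numeric(scale(37.5 * d$y)), s = 5,
                  l1 = 0.5, l2 = 0.5)
  expect_equal(f1$w1, f2$w1, tolerance = 1e-8)
  expect_equal(f1$w2, f2$w2, tolerance = 1e-8)
})

test_that("the phenotype share of the objective grows with s", {
  d <- make_latent_blocks(n = 120, p1 = 10, p2 = 10, seed = 28)
  share <- vapply(c(0.5, 1, 5, 10, 20), function(s) {
    fit <- fit_smcca(d$X1, d$X2, d$y, s = s, l1 = 0.5, l2 = 0.5)
    n <- nrow(d$X1)
    ph <- s * (sum(fit$w1 * crossprod(d$X1, d$y) / (n - 1)) +
                 sum(fit$w2 * crossprod(d$X2, d$y) / (n - 1)))
    ph / fit$objective_value
  }, numeric(1))
  expect_true(all(diff(share) >= -1e-8))
})

test_that("support size is monotone in the sparsity fraction", {
  d <- make_latent_blocks(n = 100, p1 = 20, p2 = 20, k1 = 5, k2 = 5, seed = 29)
  grid <- c(0.05, 0.15, 0.25, 0.35, 0.45, 0.55)
  supp <- vapply(grid, function(l) {
    fit <- suppressWarnings(fit_smcca(d$X1, d$X2, d$y, s = 5, l1 = l, l2 = l))
    sum(fit$w1 != 0) + sum(fit$w2 != 0)
  }, numeric(1))
  expect_true(all(diff(supp) >= 0))
})

test_that("cross-validation enumerates the full penalty grid", {
  d <- make_latent_blocks(n = 60, p1 = 6, p2 = 6, seed = 30)
  grid <- c(0.05, 0.15, 0.25, 0.35, 0.45, 0.55)
  cv <- cv_select_penalties(d$X1, d$X2, d$y, s = 2, grid = grid, seed = 1)
  expect_equal(nrow(cv$table), 36)
  expect_true(all(abs(table(cv$folds) - 12) <= 1))
  best <- max(cv$table$mean_test_objective)
  chosen_val <- cv$table$mean_test_objective[
    cv$table$l1 == cv$chosen[["l1"]] & cv$table$l2 == cv$chosen[["l2"]]]
  expect_equal(chosen_val, best)

  one <- cv_select_penalties(d$X1, d$X2, d$y, s = 2, grid = 0.3, seed = 1)
  expect_equal(unname(one$chosen), c(0.3, 0.3))
})

test_that("near-noiseless CV keeps all planted features in the support", {
  cfg <- synthetic_config(n_subjects = 100, p_proteins = 12, p_metabolites = 12,
                          n_signal_1 = 4, n_signal_2 = 4,
                          latent_loading_range = c(1, 1), noise_sd = 0.01,
                          n_covariates = 0, n_run_days = 1,
                          missing_rate = 0, seed = 31)
  ds <- generate_multiomics(cfg)
  X1 <- std_cols(log(ds$proteins$values))
  X2 <- std_cols(log(ds$metabolites$values))
  y <- as.numeric(scale(ds$phenotype))
  cv <- cv_select_penalties(X1, X2, y, s = 5, seed = 2)
  fit <- fit_smcca(X1, X2, y, s = 5,
                   l1 = cv$chosen[["l1"]], l2 = cv$chosen[["l2"]])
  expect_true(all(ds$signal_idx_1 %in% which(fit$w1 != 0)))
  expect_true(all(ds$signal_idx_2 %in% which(fit$w2 != 0)))
})

test_that("similarity without subsampling equals the normalized outer product", {
  d <- make_latent_blocks(n = 60, p1 = 6, p2 = 6, seed = 32)
  sim <- build_similarity(d$X1, d$X2, d$y, s = 3, l1 = 0.5, l2 = 0.5,
                          fraction_1 = 1, fraction_2 = 1, n_subsamples = 1,
                          seed = 5)
  fit <- fit_smcca(d$X1, d$X2, d$y, s = 3, l1 = 0.5, l2 = 0.5)
  w <- c(fit$w1, fit$w2)
  O <- abs(tcrossprod(w))
  diag(O) <- 0
  O <- O / max(O)
  expect_equal(unname(sim$values), unname(O), tolerance = 1e-10)
})

test_that("similarity matrices satisfy their contract and are stable", {
  d <- make_latent_blocks(n = 120, p1 = 15, p2 = 15, k1 = 5, k2 = 5,
                          noise = 0.5, seed = 33)
  s1 <- build_similarity(d$X1, d$X2, d$y, s = 5, l1 = 0.5, l2 = 0.5,
                         n_subsamples = 200, seed = 101)
  expect_equal(s1$values, t(s1$values))
  expect_true(all(s1$values >= 0 & s1$values <= 1))
  expect_true(all(diag(s1$values) == 0))
  expect_equal(max(s1$values), 1)
  s2 <- build_similarity(d$X1, d$X2, d$y, s = 5, l1 = 0.5, l2 = 0.5,
                         n_subsamples = 200, seed = 202)
  expect_lt(norm(s1$values - s2$values, "F"), 0.1 * norm(s1$values, "F"))
})

test_that("features never selected have exactly zero similarity", {
  set.seed(34)
  ## an all-noise feature with tiny variance signal cannot enter any one-hot fit
  d <- make_latent_blocks(n = 80, p1 = 8, p2 = 8, k1 = 2, k2 = 2,
                          noise = 0.1, seed = 34)
  sim <- build_similarity(d$X1, d$X2, d$y, s = 10, l1 = 0.12, l2 = 0.12,
                          n_subsamples = 50, seed = 11)
  ## l = 0.12 -> budget max(1, 0.34) = 1: one-hot fits; most features unused
  unused <- which(rowSums(sim$values) == 0)
  expect_gt(length(unused), 0)
  for (j in unused) expect_true(all(sim$values[j, ] == 0))
})
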