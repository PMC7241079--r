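#' Pairwise correlation range diagnostic
#'
#' Computes the min/max Pearson correlations between the two omics blocks,
#' and between each block and the phenotype. When the omics-omics correlation
#' range strictly contains the omics-phenotype range, the phenotype terms are
#' at risk of being ignored by the canonical objective and raising the
#' scaling constant is recommended.
#'
#' @param X1,X2 numeric matrices (subjects x features), no missing cells.
#' @param y phenotype vector (missing allowed; handled pairwise-complete).
#' @return a `correlation_range_report` list with ranges and a logical
#'   `recommend_scaling`.
#' @export
correlation_range_report <- function(X1, X2, y) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (nrow(X1) < 3) stop("need at least 3 subjects")
  if (anyNA(X1) || anyNA(X2)) stop("omics matrices must be complete")
  r12 <- stats::cor(X1, X2)
  r1y <- drop(stats::cor(X1, y, use = "pairwise.complete.obs"))
  r2y <- drop(stats::cor(X2, y, use = "pairwise.complete.obs"))
  rng <- function(v) { v <- v[is.finite(v)]; c(min = min(v), max = max(v)) }
  omics_omics <- rng(r12)
  omics_pheno <- rng(c(r1y, r2y))
  recommend <- omics_omics["min"] < omics_pheno["min"] &&
    omics_omics["max"] > omics_pheno["max"]
  structure(list(omics_omics = omics_omics,
                 omics_phenotype_1 = rng(r1y),
                 omics_phenotype_2 = rng(r2y),
                 omics_phenotype = omics_pheno,
                 recommend_scaling = unname(recommend)),
            class = "correlation_range_report")
}

#' Project a vector onto the L1/L2 constraint set
#'
#' Solves `argmax w'v` over the set `{w : ||w||_2 <= 1, ||w||_1 <= c}` by
#' soft-thresholding `S(v, d) = sign(v) max(|v| - d, 0)` rescaled to unit L2
#' norm, with the threshold `d >= 0` chosen by bisection as the smallest
#' value making the L1 constraint feasible (tolerance 1e-10). `d = 0` when
#' the plain unit-normalized vector is already feasible.
#'
#' @param v numeric vector.
#' @param c L1 budget, must be `>= 1` (with a unit L2 norm, an L1 norm below
#'   1 is unattainable); `c = 1` yields a one-hot vector at the largest
#'   `|v|`, ties broken by lowest index.
#' @return the projected unit vector; an all-zero `v` returns an all-zero
#'   vector with attribute `zero = TRUE`.
#' @export
project_l1_l2 <- function(v, c) {
  if (c < 1) stop("L1 budget c must be >= 1 (got ", c, ")")
  v <- as.numeric(v)
  if (all(v == 0)) return(structure(v, zero = TRUE))
  onehot <- function() {
    i <- which.max(abs(v))          # which.max takes the first maximum
    w <- numeric(length(v))
    w[i] <- sign(v[i])
    w
  }
  if (c == 1) return(onehot())
  soft <- function(d) {
    w <- sign(v) * pmax(abs(v) - d, 0)
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) return(NULL)
    w / nrm
  }
  w0 <- v / sqrt(sum(v^2))
  if (sum(abs(w0)) <= c + 1e-10) return(w0)
  lo <- 0
  hi <- max(abs(v))
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    w <- soft(mid)
    l1 <- if (is.null(w)) 1 else sum(abs(w))   # fully thresholded -> one-hot limit
    if (l1 > c) lo <- mid else hi <- mid
    if (hi - lo < 1e-12 * max(1, max(abs(v)))) break
  }
  w <- soft(hi)
  if (is.null(w)) return(onehot())
  ## polish: ensure the L1 constraint holds to tolerance
  if (sum(abs(w)) > c + 1e-8) {
    hi2 <- max(abs(v)); lo2 <- hi
    for (iter in 1:100) {
      mid <- (lo2 + hi2) / 2
      wm <- soft(mid)
      if (is.null(wm)) { hi2 <- mid; next }
      if (sum(abs(wm)) > c) lo2 <- mid else { hi2 <- mid; w <- wm }
    }
  }
  w
}

#' Weighted canonical objective
#'
#' Evaluates `J = w1' S12 w2 + s (w1' s1y + w2' s2y)` where `S12 = X1'X2 /
#' (n-1)` and `sky = Xk'y / (n-1)`; with standardized columns all entries are
#' Pearson correlations. `s` is the scaling constant prioritizing
#' omics-phenotype correlation over omics-omics correlation.
#'
#' @param w1,w2 weight vectors for the two blocks.
#' @param X1,X2 standardized matrices; `y` standardized phenotype.
#' @param s nonnegative scaling constant.
#' @return the scalar objective value.
#' @export
weighted_objective <- function(w1, w2, X1, X2, y, s) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  n <- nrow(X1)
  if (nrow(X2) != n || length(y) != n)
    stop("misaligned dimensions: X1, X2 and y must share subjects")
  if (length(w1) != ncol(X1) || length(w2) != ncol(X2))
    stop("misaligned dimensions: weight lengths must match feature counts")
  S12 <- crossprod(X1, X2) / (n - 1)
  s1y <- drop(crossprod(X1, y)) / (n - 1)
  s2y <- drop(crossprod(X2, y)) / (n - 1)
  drop(t(w1) %*% S12 %*% w2) + s * (sum(w1 * s1y) + sum(w2 * s2y))
}

#' Fit sparse multiple canonical correlation weights
#'
#' Block coordinate ascent on the weighted objective: holding one block's
#' weights fixed, the other block's update is the L1/L2 projection of its
#' gradient (`S12 w2 + s s1y`, resp. `S12' w1 + s s2y`). The phenotype enters
#' as a fixed scalar third block with weight +1, so only the two omics weight
#' vectors are optimized. The objective is non-decreasing across iterations;
#' the fit stops when the largest weight change falls below `tol`.
#'
#' @param X1,X2 standardized matrices (subjects x features).
#' @param y standardized phenotype (no missing values here; subset upstream).
#' @param s scaling constant (>= 0).
#' @param l1,l2 sparsity fractions in (0, 1]; the L1 budget for block k is
#'   `max(1, lk * sqrt(pk))` (clamped so small blocks remain feasible).
#' @param max_iter,tol iteration cap and convergence tolerance.
#' @return a `canonical_weights` list: `w1`, `w2`, `objective_value`,
#'   `objective_trace`, `n_iterations`, `converged`.
#' @export
fit_smcca <- function(X1, X2, y, s = 1, l1 = 0.5, l2 = 0.5,
                      max_iter = 200, tol = 1e-6) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  n <- nrow(X1)
  if (n < 3) stop("need at least 3 subjects")
  if (l1 <= 0 || l1 > 1 || l2 <= 0 || l2 > 1)
    stop("sparsity fractions must lie in (0, 1]")
  p1 <- ncol(X1); p2 <- ncol(X2)
  c1 <- max(1, l1 * sqrt(p1))
  c2 <- max(1, l2 * sqrt(p2))
  S12 <- crossprod(X1, X2) / (n - 1)
  s1y <- drop(crossprod(X1, y)) / (n - 1)
  s2y <- drop(crossprod(X2, y)) / (n - 1)
  obj <- function(w1, w2)
    drop(t(w1) %*% S12 %*% w2) + s * (sum(w1 * s1y) + sum(w2 * s2y))

  ## deterministic init: column-sums of |S12| (one entry per block-2 feature)
  w2 <- colSums(abs(S12))
  if (all(w2 == 0)) w2 <- rep(1, p2)
  w2 <- w2 / sqrt(sum(w2^2))
  w1 <- rep(0, p1)
  trace <- numeric(0)
  last <- -Inf
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    w1_new <- project_l1_l2(drop(S12 %*% w2) + s * s1y, c1)
    w2_new <- project_l1_l2(drop(crossprod(S12, w1_new)) + s * s2y, c2)
    val <- obj(w1_new, w2_new)
    if (length(trace) &&
        val < trace[length(trace)] - 1e-8 * max(1, abs(trace[length(trace)])))
      warning("objective decreased by ", trace[length(trace)] - val)
    trace <- c(trace, val)
    delta <- max(max(abs(w1_new - w1)), max(abs(w2_new - w2)))
    w1 <- w1_new; w2 <- w2_new
    if (delta < tol) { converged <- TRUE; break }
    last <- val
  }
  if (!converged)
    warning("fit_smcca did not converge in ", max_iter, " iterations")
  if (all(w1 == 0) && all(w2 == 0))
    warning("degenerate fit: both weight vectors are all-zero")
  structure(list(w1 = w1, w2 = w2, objective_value = obj(w1, w2),
                 objective_trace = trace, n_iterations = it,
                 converged = converged, s = s, l1 = l1, l2 = l2),
            class = "canonical_weights")
}

## k-fold assignments with sizes differing by at most 1, seeded.
make_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Select sparsity penalties by k-fold cross-validation
#'
#' Every (l1, l2) pair from `grid` is evaluated. Per fold, weights are
#' fitted on the training subjects and the weighted objective is evaluated
#' with the trained weights on the independently standardized held-out
#' split. The chosen pair maximizes the mean held-out objective over folds
#' and repeats — the pair whose canonical directions generalize best; ties
#' go to the smaller `l1 + l2`, then the smaller `l1`. The table also
#' records the relative train/test objective gap
#' `|J_train - J_test| / |J_train|` as an overfit diagnostic; the gap is
#' not used for selection because its minimum is flat across support sizes
#' (any non-overfitting support, including a single feature, attains it),
#' so it cannot separate too-sparse fits from well-sized ones.
#'
#' The fold assignment is repeated `n_repeats` times with independent
#' seeded partitions and the per-pair criteria are averaged across
#' repeats, the standard variance-reduction remedy for a 36-pair grid
#' whose criterion surface is locally flat.
#'
#' @param X1,X2 standardized matrices; `y` standardized phenotype.
#' @param s scaling constant.
#' @param grid numeric vector of candidate sparsity fractions in (0, 1].
#' @param k_folds number of folds (default 5).
#' @param n_repeats independent fold partitions to average over (default 5).
#' @param seed integer seed for the fold assignments.
#' @return a `cv_result` list: `table` (one row per pair with the mean
#'   held-out objective and the relative train/test gap), `chosen`
#'   (l1, l2), `folds` (assignment of the first repeat).
#' @export
cv_select_penalties <- function(X1, X2, y, s = 1,
                                grid = c(0.05, 0.15, 0.25, 0.35, 0.45, 0.55),
                                k_folds = 5, n_repeats = 5, seed = 1L) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  n <- nrow(X1)
  if (n < k_folds) stop("need at least k_folds subjects")
  if (any(grid <= 0 | grid > 1)) stop("grid values must lie in (0, 1]")
  pairs <- expand.grid(l1 = grid, l2 = grid, KEEP.OUT.ATTRS = FALSE)
  jte_mat <- matrix(0, nrow(pairs), n_repeats)
  gap_mat <- matrix(0, nrow(pairs), n_repeats)
  folds1 <- NULL
  for (r in seq_len(n_repeats)) {
    folds <- make_folds(n, k_folds, substream_seed(seed, paste0("cvrep", r)))
    if (r == 1) folds1 <- folds
    if (min(table(folds)) < 3) stop("a fold has fewer than 3 subjects")
    ## pre-standardize the splits once per repeat
    splits <- lapply(seq_len(k_folds), function(f) {
      tr <- folds != f
      list(X1tr = standardize_columns(X1[tr, , drop = FALSE], zero_ok = TRUE),
           X2tr = standardize_columns(X2[tr, , drop = FALSE], zero_ok = TRUE),
           ytr = as.numeric(scale(y[tr])),
           X1te = standardize_columns(X1[!tr, , drop = FALSE], zero_ok = TRUE),
           X2te = standardize_columns(X2[!tr, , drop = FALSE], zero_ok = TRUE),
           yte = as.numeric(scale(y[!tr])))
    })
    for (i in seq_len(nrow(pairs))) {
      l1 <- pairs$l1[i]; l2 <- pairs$l2[i]
      fold_vals <- vapply(splits, function(sp) {
        fit <- suppressWarnings(
          fit_smcca(sp$X1tr, sp$X2tr, sp$ytr, s = s, l1 = l1, l2 = l2))
        jtr <- weighted_objective(fit$w1, fit$w2, sp$X1tr, sp$X2tr, sp$ytr, s)
        jte <- weighted_objective(fit$w1, fit$w2, sp$X1te, sp$X2te, sp$yte, s)
        c(jte, abs(jtr - jte) / max(abs(jtr), .Machine$double.eps))
      }, numeric(2))
      jte_mat[i, r] <- mean(fold_vals[1, ])
      gap_mat[i, r] <- mean(fold_vals[2, ])
    }
  }
  jte <- rowMeans(jte_mat)
  tab <- cbind(pairs, mean_test_objective = jte,
               mean_relative_gap = rowMeans(gap_mat))
  best <- max(jte)
  cand <- which(jte >= best - 1e-12)
  cand <- cand[order(pairs$l1[cand] + pairs$l2[cand], pairs$l1[cand])]
  chosen <- cand[1]
  structure(list(table = tab,
                 chosen = c(l1 = pairs$l1[chosen], l2 = pairs$l2[chosen]),
                 folds = folds1, s = s),
            class = "cv_result")
}

#' Consensus similarity matrix by feature subsampling
#'
#' Repeatedly subsamples `ceiling(fraction_k * p_k)` features per block
#' without replacement, fits SmCCA on the subsampled columns, embeds the
#' weights into full-length vectors (zeros elsewhere), and accumulates the
#' absolute outer product of the concatenated weight vector. The average
#' over replicates is normalized by its maximum off-diagonal entry (skipped
#' when all-zero), the diagonal is set to zero, and edge signs are taken
#' from the pairwise Pearson correlations of the full data.
#'
#' @param X1,X2 standardized matrices; `y` standardized phenotype.
#' @param s scaling constant; `l1`, `l2` sparsity fractions.
#' @param fraction_1,fraction_2 feature subsampling proportions in (0, 1].
#' @param n_subsamples number of replicates.
#' @param seed integer seed.
#' @param feature_kind optional kind label per concatenated feature.
#' @return a `similarity_matrix` list: `values` ((p1+p2) square, in [0, 1],
#'   zero diagonal), `signs` (+/-1), `feature_ids`, `feature_kind`,
#'   `p1`, `p2`.
#' @export
build_similarity <- function(X1, X2, y, s = 1, l1 = 0.5, l2 = 0.5,
                             fraction_1 = 0.7, fraction_2 = 0.7,
                             n_subsamples = 100, seed = 1L,
                             feature_kind = NULL) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  p1 <- ncol(X1); p2 <- ncol(X2)
  m1 <- ceiling(fraction_1 * p1)
  m2 <- ceiling(fraction_2 * p2)
  if (m1 < 2 || m2 < 2)
    stop("subsample size below 2 features; raise fraction or block size")
  ids <- c(colnames(X1) %||% paste0("x1_", seq_len(p1)),
           colnames(X2) %||% paste0("x2_", seq_len(p2)))
  if (is.null(feature_kind))
    feature_kind <- c(rep("protein", p1), rep("metabolite", p2))
  acc <- matrix(0, p1 + p2, p1 + p2)
  set.seed(seed)
  for (b in seq_len(n_subsamples)) {
    i1 <- sort(sample.int(p1, m1))
    i2 <- sort(sample.int(p2, m2))
    fit <- suppressWarnings(
      fit_smcca(X1[, i1, drop = FALSE], X2[, i2, drop = FALSE], y,
                s = s, l1 = l1, l2 = l2))
    w <- numeric(p1 + p2)
    w[i1] <- fit$w1
    w[p1 + i2] <- fit$w2
    acc <- acc + abs(tcrossprod(w))
  }
  A <- acc / n_subsamples
  diag(A) <- 0
  mx <- max(A)
  if (mx > 0) A <- A / mx
  A <- (A + t(A)) / 2   # enforce exact symmetry against rounding
  Xall <- cbind(X1, X2)
  signs <- sign(stats::cor(Xall))
  signs[signs == 0] <- 1
  dimnames(A) <- list(ids, ids)
  structure(list(values = A, signs = signs, feature_ids = ids,
                 feature_kind = feature_kind, p1 = p1, p2 = p2,
                 s = s, l1 = l1, l2 = l2, n_subsamples = n_subsamples,
                 fraction_1 = fraction_1, fraction_2 = fraction_2,
                 seed = seed),
            class = "similarity_matrix")
}

#' Write a similarity matrix with a sidecar JSON
#'
#' @param sim a `similarity_matrix`.
#' @param path output path for the delimited square matrix; the sidecar JSON
#'   (scaling, penalties, subsampling scheme, seed) is written next to it
#'   with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path) {
  utils::write.table(sim$values, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  meta <- sim[c("s", "l1", "l2", "n_subsamples", "fraction_1", "fraction_2",
                "seed", "p1", "p2")]
  jsonlite::write_json(meta, paste0(sub("\\.[^.]*$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
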