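#' Preprocessing configuration
#'
#' @param outlier_z_cutoff SD cutoff for aggregate subject outlier removal
#'   (default 3.5).
#' @param max_missing_fraction maximum tolerated per-feature missing fraction;
#'   features strictly above it are dropped (default 0.20).
#' @param knn_k number of neighbor features for imputation (default 10).
#' @param standardize_phenotype whether pipeline runs center/scale the
#'   phenotype (default TRUE).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(outlier_z_cutoff = 3.5,
                              max_missing_fraction = 0.20, knn_k = 10,
                              standardize_phenotype = TRUE) {
  if (max_missing_fraction <= 0 || max_missing_fraction >= 1)
    stop("max_missing_fraction must lie in (0, 1)")
  if (knn_k < 1) stop("knn_k must be >= 1")
  structure(list(outlier_z_cutoff = outlier_z_cutoff,
                 max_missing_fraction = max_missing_fraction,
                 knn_k = as.integer(knn_k),
                 standardize_phenotype = isTRUE(standardize_phenotype)),
            class = "preprocess_config")
}

#' Run-day median normalization
#'
#' For every feature, each observed intensity on run day `d` is divided by
#' that feature's day-`d` median and multiplied by the feature's overall
#' median, medians taken over observed values only. Corrects day-level
#' multiplicative batch effects; a single run day leaves the block unchanged.
#'
#' @param block an [omics_block] with `run_day` labels and positive observed
#'   intensities.
#' @return the normalized [omics_block].
#' @export
runday_normalize <- function(block) {
  stopifnot(inherits(block, "omics_block"))
  if (is.null(block$run_day))
    stop("runday_normalize requires run_day labels")
  V <- block$values
  if (any(V <= 0, na.rm = TRUE))
    stop("runday_normalize requires positive observed intensities")
  days <- unique(block$run_day)
  overall <- apply(V, 2, stats::median, na.rm = TRUE)
  out <- V
  for (d in days) {
    rows <- which(block$run_day == d)
    med_d <- apply(V[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    bad <- which(!is.finite(med_d) | med_d == 0)
    if (length(bad))
      stop("run-day median undefined or zero for feature '",
           block$feature_ids[bad[1]], "' on day '", d, "'")
    out[rows, ] <- sweep(sweep(V[rows, , drop = FALSE], 2, med_d, "/"),
                         2, overall, "*")
  }
  block$values <- out
  block
}

#' Remove aggregate-outlier subjects
#'
#' Features are z-scored across subjects (observed values only); each
#' subject's aggregate score is the median of their feature z-scores.
#' Subjects whose aggregate lies more than `outlier_z_cutoff` SDs from the
#' cohort mean of the aggregates are removed.
#'
#' @param block an [omics_block] with at least 3 subjects.
#' @param config a [preprocess_config()].
#' @return a list with the reduced `block` and the `removed` subject ids.
#' @export
remove_outlier_subjects <- function(block, config = preprocess_config()) {
  stopifnot(inherits(block, "omics_block"))
  V <- block$values
  if (nrow(V) < 3) stop("need at least 3 subjects")
  mu <- colMeans(V, na.rm = TRUE)
  sdv <- apply(V, 2, stats::sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1   # constant features contribute z = 0
  Z <- sweep(sweep(V, 2, mu, "-"), 2, sdv, "/")
  agg <- apply(Z, 1, stats::median, na.rm = TRUE)
  centre <- mean(agg)
  spread <- stats::sd(agg)
  flagged <- if (!is.finite(spread) || spread == 0) rep(FALSE, length(agg))
             else abs(agg - centre) > config$outlier_z_cutoff * spread
  if (all(flagged))
    stop("degenerate data: every subject flagged as an outlier")
  keep <- which(!flagged)
  list(block = block_subset(block, subjects = keep),
       removed = block$subject_ids[flagged])
}

#' Drop features with excessive missingness
#'
#' Features whose missing fraction is strictly greater than
#' `max_missing_fraction` are removed; survivor order is preserved.
#'
#' @param block an [omics_block].
#' @param config a [preprocess_config()].
#' @return a list with the filtered `block` and the `dropped` feature ids.
#' @export
filter_missingness <- function(block, config = preprocess_config()) {
  stopifnot(inherits(block, "omics_block"))
  frac <- colMeans(is.na(block$values))
  drop <- frac > config$max_missing_fraction
  if (all(drop)) stop("all features exceed the missingness cutoff")
  list(block = block_subset(block, features = which(!drop)),
       dropped = block$feature_ids[drop])
}

#' K-nearest-neighbor imputation across features
#'
#' Each missing cell (subject i, feature j) is replaced by the unweighted
#' mean, at subject i, of the `knn_k` features nearest to feature j. Distance
#' between two features is the Euclidean distance over their co-observed
#' subjects; a candidate neighbor must be observed at subject i. When fewer
#' than `knn_k` features qualify, all qualifying features are used.
#'
#' @param block an [omics_block], already missingness-filtered; every feature
#'   must have at least one observed value.
#' @param config a [preprocess_config()].
#' @return the imputed [omics_block] (no missing cells).
#' @export
knn_impute <- function(block, config = preprocess_config()) {
  stopifnot(inherits(block, "omics_block"))
  V <- block$values
  if (!anyNA(V)) return(block)
  obs <- !is.na(V)
  if (any(colSums(obs) == 0))
    stop("feature with zero observed values: ",
         block$feature_ids[which(colSums(obs) == 0)[1]])
  k <- config$knn_k
  p <- ncol(V)
  need <- which(colSums(!obs) > 0)
  for (j in need) {
    ## distances from feature j to all other features over co-observed rows
    dj <- rep(NA_real_, p)
    for (l in seq_len(p)) {
      if (l == j) next
      shared <- obs[, j] & obs[, l]
      if (!any(shared)) next
      dj[l] <- sqrt(sum((V[shared, j] - V[shared, l])^2))
    }
    miss_rows <- which(!obs[, j])
    ord <- order(dj, seq_len(p), na.last = NA)   # ties by lowest index
    for (i in miss_rows) {
      cand <- ord[obs[i, ord]]
      if (!length(cand)) {
        ## no neighbor observed here: fall back to the feature's observed mean
        V[i, j] <- mean(V[obs[, j], j])
      } else {
        use <- cand[seq_len(min(k, length(cand)))]
        V[i, j] <- mean(V[i, use])
      }
    }
  }
  block$values <- V
  block
}

#' Natural-log transform and column standardization
#'
#' Values must be strictly positive and complete. Each column is natural-log
#' transformed, then centered and scaled to unit SD (n-1 denominator).
#'
#' @param block an [omics_block].
#' @return the transformed [omics_block].
#' @export
log_standardize <- function(block) {
  stopifnot(inherits(block, "omics_block"))
  V <- block$values
  if (anyNA(V)) stop("log_standardize requires a complete matrix; impute first")
  if (any(V <= 0)) {
    idx <- which(V <= 0, arr.ind = TRUE)[1, ]
    stop("nonpositive value at subject '", block$subject_ids[idx[1]],
         "', feature '", block$feature_ids[idx[2]], "'")
  }
  L <- log(V)
  sdv <- apply(L, 2, stats::sd)
  if (any(sdv < .Machine$double.eps^0.5)) {
    bad <- block$feature_ids[sdv < .Machine$double.eps^0.5]
    stop("zero-variance feature(s) after log transform: ",
         paste(bad, collapse = ", "))
  }
  block$values <- standardize_columns(L)
  block
}

#' Residualize features on covariates
#'
#' Replaces each feature column with its ordinary-least-squares residual on
#' an intercept plus the covariate columns, then re-standardizes the
#' residuals so adjusted and unadjusted branches feed identically scaled
#' inputs downstream.
#'
#' @param block an [omics_block] with standardized, complete values.
#' @param covariates numeric matrix (subjects x covariates) aligned with the
#'   block's subjects, no missing values.
#' @return the adjusted [omics_block].
#' @export
residualize_covariates <- function(block, covariates) {
  stopifnot(inherits(block, "omics_block"))
  C <- as.matrix(covariates)
  if (nrow(C) != nrow(block$values))
    stop("covariate rows (", nrow(C), ") do not match subjects (",
         nrow(block$values), ")")
  if (anyNA(C)) stop("covariate matrix contains missing values")
  X <- cbind(`(Intercept)` = 1, C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  resid <- qr.resid(qrX, block$values)
  block$values <- standardize_columns(resid)
  block
}

#' Center and scale a phenotype vector
#'
#' Non-missing entries are centered and scaled to unit SD (n-1 denominator);
#' missing entries are preserved as missing.
#'
#' @param values numeric vector with at least 2 non-missing values of
#'   nonzero variance.
#' @return the standardized vector.
#' @export
standardize_phenotype <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least 2 non-missing phenotype values")
  s <- stats::sd(values[ok])
  if (!is.finite(s) || s == 0) stop("phenotype has zero variance")
  out <- values
  out[ok] <- (values[ok] - mean(values[ok])) / s
  out
}

#' Run the full preprocessing chain on one omics block
#'
#' Fixed order: run-day normalization (when run-day labels are present),
#' aggregate-outlier subject removal, missingness filtering, KNN imputation,
#' log transform + standardization, and optional covariate residualization.
#'
#' @param block an [omics_block] on the raw intensity scale.
#' @param config a [preprocess_config()].
#' @param covariates optional covariate matrix; when supplied the block is
#'   residualized on it as the final step.
#' @param remove_outliers whether to run the aggregate-outlier step (on by
#'   default for metabolite-style blocks with run days).
#' @return a list: `block` (processed), `report` (removed subjects, dropped
#'   features, imputed cell count).
#' @export
preprocess_block <- function(block, config = preprocess_config(),
                             covariates = NULL,
                             remove_outliers = !is.null(block$run_day)) {
  report <- list(removed_subjects = character(0),
                 dropped_features = character(0), imputed_cells = 0L)
  if (!is.null(block$run_day)) block <- runday_normalize(block)
  if (remove_outliers) {
    out <- remove_outlier_subjects(block, config)
    block <- out$block
    report$removed_subjects <- out$removed
  }
  filt <- filter_missingness(block, config)
  block <- filt$block
  report$dropped_features <- filt$dropped
  report$imputed_cells <- sum(is.na(block$values))
  block <- knn_impute(block, config)
  block <- log_standardize(block)
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (!is.null(rownames(C)))
      C <- C[block$subject_ids, , drop = FALSE]
    else if (length(report$removed_subjects))
      stop("covariates need rownames to align after outlier removal")
    block <- residualize_covariates(block, C)
  }
  list(block = block, report = report)
}
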