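#' Spirometric COPD grading (GOLD / PRISm)
#'
#' Classifies subjects from percent-predicted FEV1 and the FEV1/FVC ratio:
#' GOLD0 (FEV1 >= 80, ratio >= 0.7), GOLD1 (FEV1 >= 80, ratio < 0.7),
#' GOLD2 (50 <= FEV1 < 80, ratio < 0.7), GOLD3 (30 <= FEV1 < 50,
#' ratio < 0.7), GOLD4 (FEV1 < 30, ratio < 0.7), and PRISm (preserved-ratio
#' impaired spirometry: FEV1 < 80, ratio >= 0.7). Missing inputs give
#' MISSING.
#'
#' @param fev1_pct percent-predicted FEV1 (vectorized).
#' @param ratio FEV1/FVC ratio (vectorized).
#' @return a character vector over {GOLD0..GOLD4, PRISm, MISSING}.
#' @export
classify_gold <- function(fev1_pct, ratio) {
  n <- max(length(fev1_pct), length(ratio))
  fev1_pct <- rep_len(fev1_pct, n)
  ratio <- rep_len(ratio, n)
  out <- character(n)
  for (i in seq_len(n)) {
    f <- fev1_pct[i]; r <- ratio[i]
    out[i] <- if (is.na(f) || is.na(r)) "MISSING"
    else if (r >= 0.7) { if (f >= 80) "GOLD0" else "PRISm" }
    else if (f >= 80) "GOLD1"
    else if (f >= 50) "GOLD2"
    else if (f >= 30) "GOLD3"
    else "GOLD4"
  }
  out
}

#' Emphysema severity bins
#'
#' Bins percent emphysema into control [0, 5), mild [5, 10), moderate
#' [10, 20], and severe (> 20). The bins partition [0, Inf); the upper bound
#' of moderate is inclusive so that "severe" means strictly more than 20
#' percent.
#'
#' @param pct percent emphysema, nonnegative (vectorized; NA passes through).
#' @return a character vector over {control, mild, moderate, severe}.
#' @export
classify_emphysema_severity <- function(pct) {
  if (any(pct < 0, na.rm = TRUE)) stop("percent emphysema must be >= 0")
  ifelse(is.na(pct), NA_character_,
         ifelse(pct < 5, "control",
                ifelse(pct < 10, "mild",
                       ifelse(pct <= 20, "moderate", "severe"))))
}

#' Compare adjusted and unadjusted network node sets
#'
#' Builds the 2x2 membership table of two node sets over a stated background
#' universe (features that entered the analysis) and tests overlap
#' enrichment with a one-sided Fisher's exact test; the sample odds ratio
#' `(a d) / (b c)` is reported.
#'
#' @param adjusted,unadjusted character vectors of node ids, each a subset of
#'   `universe`.
#' @param universe character vector: the background feature universe.
#' @return an `overlap_table` list: `table` (2x2 matrix), `odds_ratio`,
#'   `p_value`, `sidedness`.
#' @export
compare_networks <- function(adjusted, unadjusted, universe) {
  adjusted <- unique(as.character(adjusted))
  unadjusted <- unique(as.character(unadjusted))
  universe <- unique(as.character(universe))
  out1 <- setdiff(adjusted, universe)
  out2 <- setdiff(unadjusted, universe)
  if (length(out1) || length(out2))
    stop("node ids outside the universe: ",
         paste(c(out1, out2), collapse = ", "))
  a <- length(intersect(adjusted, unadjusted))
  b <- length(setdiff(adjusted, unadjusted))
  cc <- length(setdiff(unadjusted, adjusted))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, cc, b, d), 2, 2,
                dimnames = list(adjusted = c("in", "out"),
                                unadjusted = c("in", "out")))
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  or <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
  structure(list(table = tab, odds_ratio = or, p_value = p,
                 sidedness = "greater"),
            class = "overlap_table")
}

#' Flag phenotype-significant features
#'
#' Per-feature two-sided correlation p-values via the t transform,
#' Benjamini-Hochberg adjusted across features. A feature is significant
#' when both |r| exceeds `r_cutoff` and the adjusted p-value is below
#' `fdr_cutoff` (dual criterion).
#'
#' @param r numeric vector of Pearson correlations, |r| <= 1.
#' @param n number of subjects used for each correlation (n >= 3).
#' @param r_cutoff absolute-correlation cutoff (default 0.15).
#' @param fdr_cutoff adjusted-p cutoff (default 0.001).
#' @return a data.frame: `r`, `p_value`, `p_adjusted`, `significant`.
#' @export
feature_significance <- function(r, n, r_cutoff = 0.15, fdr_cutoff = 0.001) {
  if (any(abs(r) > 1)) stop("|r| must be <= 1")
  if (n < 3) stop("n must be >= 3")
  p <- cor_pvalue(r, n)
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(r = r, p_value = p, p_adjusted = padj,
             significant = abs(r) > r_cutoff & padj < fdr_cutoff)
}

#' Subgroup analysis of network PC1 scores
#'
#' One-way ANOVA of PC1 scores across cohort subgroups, followed by Tukey's
#' honest significant difference test for the pairwise comparisons (via the
#' studentized range distribution). With exactly two groups the Tukey
#' comparison coincides with the pooled two-sample t-test.
#'
#' @param pc1 numeric vector of PC1 scores.
#' @param groups group labels (factor or character), each group with at
#'   least 2 members; at least 2 groups.
#' @return a `subgroup_result` list: `group_sizes`, `anova_F`, `anova_p`,
#'   `tukey` (data.frame comparison, diff, p_adjusted).
#' @export
subgroup_pc1_analysis <- function(pc1, groups) {
  ok <- !is.na(pc1) & !is.na(groups)
  pc1 <- pc1[ok]
  groups <- factor(as.character(groups[ok]))
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2))
    stop("group(s) with fewer than 2 members: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  fit <- stats::aov(pc1 ~ groups)
  av <- summary(fit)[[1]]
  Fv <- av[["F value"]][1]
  pv <- av[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$groups
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      p_adjusted = tk[, "p adj"],
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(group_sizes = sizes, anova_F = Fv, anova_p = pv,
                 tukey = tukey),
            class = "subgroup_result")
}

#' Heart-disease composite indicator
#'
#' Boolean OR across the available self-reported cardiovascular indicator
#' columns (e.g. atrial fibrillation, congestive heart failure, coronary
#' artery disease, heart attack, angioplasty, bypass graft) and a coronary
#' artery calcium score above `cac_cutoff`. Columns named but absent from
#' the table are treated as all-FALSE with a warning.
#'
#' @param clinical a data.frame.
#' @param indicator_cols character vector of 0/1 indicator column names.
#' @param cac_col optional Agatston-score column name.
#' @param cac_cutoff calcium score threshold (default 100).
#' @return an integer 0/1 vector.
#' @export
heart_disease_composite <- function(clinical, indicator_cols,
                                    cac_col = NULL, cac_cutoff = 100) {
  present <- intersect(indicator_cols, names(clinical))
  absent <- setdiff(indicator_cols, names(clinical))
  if (length(absent))
    warning("missing indicator column(s) treated as FALSE: ",
            paste(absent, collapse = ", "))
  acc <- rep(FALSE, nrow(clinical))
  for (col in present)
    acc <- acc | (!is.na(clinical[[col]]) & clinical[[col]] != 0)
  if (!is.null(cac_col) && cac_col %in% names(clinical))
    acc <- acc | (!is.na(clinical[[cac_col]]) & clinical[[cac_col]] > cac_cutoff)
  as.integer(acc)
}
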