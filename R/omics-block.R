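#' Construct an omics block
#'
#' An `omics_block` is the basic data container: a subjects x features numeric
#' matrix with unique subject and feature identifiers, a feature-kind label
#' (`"protein"` or `"metabolite"`) per feature, and optionally a per-subject
#' run-day label (metabolomics batches). Missing values (`NA`) are allowed
#' before imputation.
#'
#' @param values numeric matrix, subjects in rows, features in columns.
#' @param subject_ids character vector of unique subject identifiers
#'   (default: rownames of `values`).
#' @param feature_ids character vector of unique feature identifiers
#'   (default: colnames of `values`).
#' @param feature_kind either a single kind recycled to all features or a
#'   vector with one of `"protein"`, `"metabolite"` per feature.
#' @param run_day optional per-subject batch label (character or factor).
#' @return an object of class `omics_block`: a list with elements `values`,
#'   `subject_ids`, `feature_ids`, `feature_kind`, `run_day`.
#' @export
omics_block <- function(values, subject_ids = rownames(values),
                        feature_ids = colnames(values),
                        feature_kind = "protein", run_day = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(values)))
  subject_ids <- as.character(subject_ids)
  feature_ids <- as.character(feature_ids)
  if (length(subject_ids) != nrow(values))
    stop("subject_ids length (", length(subject_ids),
         ") does not match number of rows (", nrow(values), ")")
  if (length(feature_ids) != ncol(values))
    stop("feature_ids length (", length(feature_ids),
         ") does not match number of columns (", ncol(values), ")")
  if (anyDuplicated(subject_ids))
    stop("duplicate subject ids: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  feature_kind <- as.character(feature_kind)
  if (length(feature_kind) == 1L)
    feature_kind <- rep(feature_kind, ncol(values))
  if (length(feature_kind) != ncol(values))
    stop("feature_kind must have length 1 or ncol(values)")
  bad <- setdiff(unique(feature_kind), c("protein", "metabolite"))
  if (length(bad))
    stop("unknown feature kind(s): ", paste(bad, collapse = ", "))
  if (!is.null(run_day)) {
    run_day <- as.character(run_day)
    if (length(run_day) != nrow(values))
      stop("run_day must have one label per subject")
  }
  rownames(values) <- subject_ids
  colnames(values) <- feature_ids
  structure(list(values = values, subject_ids = subject_ids,
                 feature_ids = feature_ids, feature_kind = feature_kind,
                 run_day = run_day),
            class = "omics_block")
}

#' @export
print.omics_block <- function(x, ...) {
  nk <- table(factor(x$feature_kind, levels = c("protein", "metabolite")))
  cat(sprintf("omics_block: %d subjects x %d features (%d protein, %d metabolite)\n",
              nrow(x$values), ncol(x$values), nk[["protein"]], nk[["metabolite"]]))
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0)
    cat(sprintf("  missing cells: %d (%.1f%%)\n", nmiss,
                100 * nmiss / length(x$values)))
  if (!is.null(x$run_day))
    cat(sprintf("  run days: %d\n", length(unique(x$run_day))))
  invisible(x)
}

#' @export
dim.omics_block <- function(x) dim(x$values)

## Replace the value matrix, keeping ids in sync. Internal.
block_subset <- function(block, subjects = NULL, features = NULL) {
  i <- if (is.null(subjects)) seq_len(nrow(block$values)) else subjects
  j <- if (is.null(features)) seq_len(ncol(block$values)) else features
  omics_block(block$values[i, j, drop = FALSE],
              subject_ids = block$subject_ids[i],
              feature_ids = block$feature_ids[j],
              feature_kind = block$feature_kind[j],
              run_day = if (is.null(block$run_day)) NULL else block$run_day[i])
}

#' Read an omics table from delimited text
#'
#' The expected layout is one header row of feature identifiers, one subject
#' per row with the subject identifier in the first column. Comma or tab
#' separation is autodetected from the header line. Empty fields and the
#' tokens `NA`, `NaN` (any case) are read as missing.
#'
#' @param path path to the delimited text file.
#' @param kind feature kind for all columns (`"protein"` or `"metabolite"`),
#'   or a vector of kinds.
#' @param run_day optional per-subject run-day labels, or the name of a column
#'   in the file holding them.
#' @return an [omics_block].
#' @export
read_omics_table <- function(path, kind = "protein", run_day = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          na.strings = c("", "NA", "NaN", "na", "nan"),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA, fill = FALSE)
  if (ncol(df) < 2) stop("parse error in ", path, ": fewer than 2 columns")
  subject_ids <- as.character(df[[1]])
  run_day_values <- NULL
  if (is.character(run_day) && length(run_day) == 1L && run_day %in% names(df)) {
    run_day_values <- as.character(df[[run_day]])
    df <- df[, setdiff(names(df), run_day), drop = FALSE]
  } else if (!is.null(run_day)) {
    run_day_values <- as.character(run_day)
  }
  feat_ids <- colnames(df)[-1]   # before subsetting: `[.data.frame` dedupes
  mat_df <- df[, -1, drop = FALSE]
  for (j in seq_along(mat_df)) {
    col <- mat_df[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad))
        stop("parse error in ", path, ": non-numeric cell at row ", bad[1] + 1L,
             ", column '", names(mat_df)[j], "'")
      col <- num
    }
    mat_df[[j]] <- col
  }
  values <- as.matrix(mat_df)
  omics_block(values, subject_ids = subject_ids, feature_ids = feat_ids,
              feature_kind = kind, run_day = run_day_values)
}

#' Write an omics block as delimited text
#'
#' Inverse of [read_omics_table()]: header row of feature ids, first column
#' `subject_id`, full-precision values, `NA` for missing cells.
#'
#' @param block an [omics_block].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_omics_table <- function(block, path, sep = "\t") {
  df <- data.frame(subject_id = block$subject_ids,
                   as.data.frame(block$values, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}
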