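#' Export a trimmed network for graph tools
#'
#' Writes a SIF edge list (`from  interacts  to`, one line per edge), a
#' GraphML file with edge attributes (weight, sign) and node attributes
#' (kind, degree, phenotype correlation), and a node-attribute table, in a
#' layout importable by Cytoscape-class viewers.
#'
#' @param net a `trimmed_network`.
#' @param dir output directory (created if absent).
#' @param node_table optional data.frame from [node_correlations()] supplying
#'   per-node phenotype correlations.
#' @param prefix file-name prefix (default "network").
#' @return named character vector of written paths, invisibly.
#' @export
write_network <- function(net, dir, node_table = NULL, prefix = "network") {
  stopifnot(inherits(net, "trimmed_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sif = file.path(dir, paste0(prefix, ".sif")),
             graphml = file.path(dir, paste0(prefix, ".graphml")),
             nodes = file.path(dir, paste0(prefix, "_nodes.tsv")))
  from_id <- net$node_ids[match(net$edges$from, net$nodes)]
  to_id <- net$node_ids[match(net$edges$to, net$nodes)]
  writeLines(paste(from_id, "interacts", to_id, sep = "\t"), paths[["sif"]])
  nodes_df <- data.frame(name = net$node_ids, kind = net$node_kind,
                         degree = as.integer(net$degrees),
                         stringsAsFactors = FALSE)
  if (!is.null(node_table)) {
    nodes_df$r <- node_table$r[match(nodes_df$name, node_table$feature_id)]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from_id, to = to_id, weight = net$edges$weight,
               sign = net$edges$sign, stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes_df)
  igraph::write_graph(g, paths[["graphml"]], format = "graphml")
  utils::write.table(nodes_df, paths[["nodes"]], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}

#' Pipeline run configuration
#'
#' @param synthetic a [synthetic_config()] to generate data, or NULL when
#'   reading `proteins_path` / `metabolites_path` / `clinical_path`.
#' @param proteins_path,metabolites_path,clinical_path,covariates_path input
#'   files (delimited text) used when `synthetic` is NULL.
#' @param phenotype_column clinical column holding the phenotype.
#' @param covariate_columns covariate column names (empty for none).
#' @param adjustment one of "adjusted", "unadjusted", "both".
#' @param s_values,tau_values,penalty_grid sweep grids.
#' @param fraction_1,fraction_2,n_subsamples subsampling scheme.
#' @param cut_height,min_rho,ratio_band module extraction and acceptance
#'   rules.
#' @param preprocess a [preprocess_config()].
#' @param out_dir output directory.
#' @param seed integer master seed; all stage randomness derives from it.
#' @return a `run_config` list.
#' @export
run_config <- function(synthetic = NULL, proteins_path = NULL,
                       metabolites_path = NULL, clinical_path = NULL,
                       covariates_path = NULL,
                       phenotype_column = "phenotype",
                       covariate_columns = character(0),
                       adjustment = c("adjusted", "unadjusted", "both"),
                       s_values = c(5, 10, 15, 20),
                       tau_values = seq(0, 0.7, by = 0.05),
                       penalty_grid = c(0.05, 0.15, 0.25, 0.35, 0.45, 0.55),
                       fraction_1 = 0.7, fraction_2 = 0.7, n_subsamples = 100,
                       cut_height = 0.999, min_rho = 0.20,
                       ratio_band = c(0.25, 4),
                       preprocess = preprocess_config(), out_dir = tempfile(),
                       seed = 1L) {
  adjustment <- match.arg(adjustment)
  if (!length(s_values) || !length(tau_values) || !length(penalty_grid))
    stop("grids must be nonempty")
  if (is.null(seed)) stop("seed must be set")
  structure(list(synthetic = synthetic, proteins_path = proteins_path,
                 metabolites_path = metabolites_path,
                 clinical_path = clinical_path,
                 covariates_path = covariates_path,
                 phenotype_column = phenotype_column,
                 covariate_columns = covariate_columns,
                 adjustment = adjustment, s_values = s_values,
                 tau_values = tau_values, penalty_grid = penalty_grid,
                 fraction_1 = fraction_1, fraction_2 = fraction_2,
                 n_subsamples = n_subsamples, cut_height = cut_height,
                 min_rho = min_rho, ratio_band = ratio_band,
                 preprocess = preprocess, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

## Run one adjustment branch: preprocess, CV, sweep, trim, summarize. Internal.
run_branch <- function(proteins, metabolites, phenotype, covariates, config,
                       branch) {
  adjust <- identical(branch, "adjusted")
  covs <- if (adjust && !is.null(covariates)) covariates else NULL
  prot <- preprocess_block(proteins, config$preprocess, covariates = covs,
                           remove_outliers = FALSE)
  met <- preprocess_block(metabolites, config$preprocess, covariates = covs,
                          remove_outliers = TRUE)
  ## intersect subjects surviving both blocks
  common <- intersect(prot$block$subject_ids, met$block$subject_ids)
  X1 <- prot$block$values[match(common, prot$block$subject_ids), , drop = FALSE]
  X2 <- met$block$values[match(common, met$block$subject_ids), , drop = FALSE]
  y <- phenotype[match(common, names(phenotype))]
  keep <- !is.na(y)
  X1 <- standardize_columns(X1[keep, , drop = FALSE], zero_ok = TRUE)
  X2 <- standardize_columns(X2[keep, , drop = FALSE], zero_ok = TRUE)
  y <- y[keep]
  if (config$preprocess$standardize_phenotype) y <- standardize_phenotype(y)

  diag_report <- correlation_range_report(X1, X2, y)
  cv <- cv_select_penalties(X1, X2, y, s = stats::median(config$s_values),
                            grid = config$penalty_grid, k_folds = 5,
                            seed = substream_seed(config$seed,
                                                  paste0("cv_", branch)))
  sweep <- hyperparameter_sweep(
    X1, X2, y, s_values = config$s_values, tau_values = config$tau_values,
    l1 = cv$chosen[["l1"]], l2 = cv$chosen[["l2"]],
    fraction_1 = config$fraction_1, fraction_2 = config$fraction_2,
    n_subsamples = config$n_subsamples, cut_height = config$cut_height,
    min_rho = config$min_rho, ratio_band = config$ratio_band,
    seed = substream_seed(config$seed, paste0("sweep_", branch)))

  Xall <- cbind(X1, X2)
  result <- list(branch = branch, preprocess_report = list(
    proteins = prot$report, metabolites = met$report),
    n_subjects = sum(keep), correlation_ranges = diag_report,
    cv = cv, sweep = sweep, X = Xall, y = y,
    feature_ids = c(colnames(X1), colnames(X2)),
    p1 = ncol(X1), p2 = ncol(X2))
  if (!is.null(sweep$selected)) {
    sel <- sweep$selected
    result$network <- sel$network
    result$summary <- sel$summary
    result$node_table <- node_correlations(sel$network, Xall, y)
    if (length(sel$complement) >= 2)
      result$complement_summary <- summarize_network(sel$complement, Xall, y)
  }
  result
}

#' Run the full analysis pipeline
#'
#' Executes, for each adjustment branch: preprocessing, correlation-range
#' diagnostics, penalty selection by 5-fold cross-validation, the
#' (scaling constant, edge threshold) sweep with consensus-similarity module
#' extraction, trimming, and PC1 phenotype summarization. When both branches
#' run, the adjusted and unadjusted node sets are compared by Fisher's exact
#' overlap test over the post-filter feature universe. All intermediates and
#' a JSON manifest are written under `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return a `pipeline_result` list: per-branch results, optional `overlap`,
#'   `manifest` and the manifest path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$synthetic)) {
    ds <- generate_multiomics(config$synthetic)
    proteins <- ds$proteins
    metabolites <- ds$metabolites
    phenotype <- stats::setNames(ds$phenotype, proteins$subject_ids)
    covariates <- ds$covariates
    rownames(covariates) <- proteins$subject_ids
    truth <- list(signal_ids_1 = proteins$feature_ids[ds$signal_idx_1],
                  signal_ids_2 = metabolites$feature_ids[ds$signal_idx_2])
  } else {
    proteins <- read_omics_table(config$proteins_path, kind = "protein")
    metabolites <- read_omics_table(config$metabolites_path,
                                    kind = "metabolite", run_day = "run_day")
    clinical <- utils::read.table(config$clinical_path, header = TRUE,
                                  sep = "\t", stringsAsFactors = FALSE)
    phenotype <- stats::setNames(clinical[[config$phenotype_column]],
                                 clinical$subject_id)
    covariates <- NULL
    if (!is.null(config$covariates_path)) {
      cv <- utils::read.table(config$covariates_path, header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
      covariates <- as.matrix(cv[, setdiff(names(cv), "subject_id"),
                                 drop = FALSE])
      rownames(covariates) <- cv$subject_id
    } else if (length(config$covariate_columns)) {
      covariates <- as.matrix(clinical[, config$covariate_columns,
                                       drop = FALSE])
      rownames(covariates) <- clinical$subject_id
    }
    truth <- NULL
  }
  ## drop subjects absent from either block
  common <- intersect(proteins$subject_ids, metabolites$subject_ids)
  dropped_subjects <- length(union(proteins$subject_ids,
                                   metabolites$subject_ids)) - length(common)
  proteins <- block_subset(proteins,
                           subjects = match(common, proteins$subject_ids))
  metabolites <- block_subset(metabolites,
                              subjects = match(common, metabolites$subject_ids))

  branches <- if (config$adjustment == "both") c("adjusted", "unadjusted")
              else config$adjustment
  results <- list()
  for (br in branches) {
    res <- run_branch(proteins, metabolites, phenotype, covariates, config, br)
    bdir <- file.path(config$out_dir, br)
    dir.create(bdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(res$sweep$table, file.path(bdir, "diagnostics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(res$network)) {
      write_network(res$network, bdir, node_table = res$node_table)
      utils::write.table(res$node_table, file.path(bdir, "node_correlations.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    results[[br]] <- res
  }

  overlap <- NULL
  if (length(results) == 2 && !is.null(results$adjusted$network) &&
      !is.null(results$unadjusted$network)) {
    universe <- union(results$adjusted$feature_ids,
                      results$unadjusted$feature_ids)
    overlap <- compare_networks(results$adjusted$network$node_ids,
                                results$unadjusted$network$node_ids, universe)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pmnet")),
    seed = config$seed, adjustment = config$adjustment,
    dropped_unmatched_subjects = dropped_subjects,
    stages = lapply(results, function(r) list(
      branch = r$branch, n_subjects = r$n_subjects,
      p1 = r$p1, p2 = r$p2,
      preprocess = r$preprocess_report,
      chosen_penalties = as.list(r$cv$chosen),
      selected = if (is.null(r$sweep$selected)) NULL else list(
        s = r$sweep$selected$s, tau = r$sweep$selected$tau,
        rho = r$summary$rho, p_value = r$summary$p_value,
        n_nodes = length(r$network$nodes),
        n_protein = r$network$n_protein,
        n_metabolite = r$network$n_metabolite,
        node_ids = r$network$node_ids))),
    overlap = if (is.null(overlap)) NULL else list(
      table = as.vector(overlap$table), odds_ratio = overlap$odds_ratio,
      p_value = overlap$p_value),
    ground_truth = truth)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  structure(list(branches = results, overlap = overlap, manifest = manifest,
                 manifest_path = manifest_path, config = config),
            class = "pipeline_result")
}
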