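#' Configuration for the synthetic multi-omics generator
#'
#' Defines a latent-factor data-generating model that mirrors the statistical
#' structure the network pipeline assumes: log-normal raw intensities, a
#' latent factor loading on a subset of features in both omics blocks and on
#' the phenotype, standard-normal covariates with linear effects on
#' log-intensities, a per-day multiplicative run-day batch factor on the
#' metabolite block, and metabolite values missing completely at random.
#'
#' @param n_subjects number of subjects.
#' @param p_proteins,p_metabolites features per block.
#' @param n_signal_1,n_signal_2 planted signal features per block.
#' @param latent_loading_range interval from which signal loadings are drawn
#'   uniformly (a length-2 numeric; equal endpoints give a fixed loading).
#' @param phenotype_loading loading of the latent factor on the phenotype.
#' @param noise_sd residual SD of feature log-intensities and the phenotype
#'   (must be > 0; pass a tiny value for near-noiseless checks).
#' @param n_covariates number of standard-normal covariates (default 6,
#'   emulating blood-cell counts).
#' @param covariate_effect_sd SD of the per-feature covariate coefficients.
#' @param n_run_days number of metabolomics run-day batches.
#' @param run_day_scale_sd SD of the per-day log-scale batch multiplier.
#' @param missing_rate metabolite missing-completely-at-random rate in [0, 1).
#' @param indicator_effect latent-factor effect (logit scale) on the binary
#'   clinical indicators produced by [generate_clinical_labels()].
#' @param seed integer seed; identical configs give identical datasets.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 500, p_proteins = 60,
                             p_metabolites = 60, n_signal_1 = 10,
                             n_signal_2 = 10,
                             latent_loading_range = c(0.5, 1),
                             phenotype_loading = 1, noise_sd = 1,
                             n_covariates = 6, covariate_effect_sd = 0.3,
                             n_run_days = 4, run_day_scale_sd = 0.2,
                             missing_rate = 0.05, indicator_effect = 0.8,
                             seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              p_proteins = as.integer(p_proteins),
              p_metabolites = as.integer(p_metabolites),
              n_signal_1 = as.integer(n_signal_1),
              n_signal_2 = as.integer(n_signal_2),
              latent_loading_range = as.numeric(latent_loading_range),
              phenotype_loading = as.numeric(phenotype_loading),
              noise_sd = as.numeric(noise_sd),
              n_covariates = as.integer(n_covariates),
              covariate_effect_sd = as.numeric(covariate_effect_sd),
              n_run_days = as.integer(n_run_days),
              run_day_scale_sd = as.numeric(run_day_scale_sd),
              missing_rate = as.numeric(missing_rate),
              indicator_effect = as.numeric(indicator_effect),
              seed = as.integer(seed))
  if (cfg$n_signal_1 > cfg$p_proteins)
    stop("invalid config: n_signal_1 exceeds p_proteins")
  if (cfg$n_signal_2 > cfg$p_metabolites)
    stop("invalid config: n_signal_2 exceeds p_metabolites")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("invalid config: missing_rate must lie in [0, 1)")
  if (cfg$noise_sd <= 0)
    stop("invalid config: noise_sd must be positive")
  if (length(cfg$latent_loading_range) != 2 ||
      diff(cfg$latent_loading_range) < 0)
    stop("invalid config: latent_loading_range must be a nondecreasing interval")
  if (cfg$n_run_days < 1) stop("invalid config: n_run_days must be >= 1")
  class(cfg) <- "synthetic_config"
  cfg
}

## Simulate one block's log-intensities: latent signal on the first columns of
## the signal index set, covariate effects on all columns, iid noise.
simulate_block_log <- function(n, p, signal_idx, z, C, cfg) {
  beta <- numeric(p)
  lr <- cfg$latent_loading_range
  beta[signal_idx] <- stats::runif(length(signal_idx), lr[1], lr[2])
  B <- matrix(stats::rnorm(cfg$n_covariates * p, sd = cfg$covariate_effect_sd),
              nrow = max(cfg$n_covariates, 0), ncol = p)
  baseline <- stats::rnorm(p, mean = 5, sd = 0.5)
  L <- outer(z, beta)
  if (cfg$n_covariates > 0) L <- L + C %*% B
  L <- L + matrix(stats::rnorm(n * p, sd = cfg$noise_sd), n, p)
  sweep(L, 2, baseline, "+")
}

#' Generate a synthetic multi-omics dataset with planted signal
#'
#' Draws a standard-normal latent factor per subject; signal features receive
#' log-intensity `beta_j * z + covariate effects + noise`, non-signal features
#' covariate effects and noise only; the phenotype is
#' `gamma * z + covariate contribution + noise`. Log-intensities are
#' exponentiated to a positive raw intensity scale; metabolite intensities are
#' multiplied by a subject-independent per-day batch factor and masked missing
#' completely at random. An FEV1/FVC-style ratio in (0, 1.2), driven by the
#' latent factor, is generated for spirometric grading tests.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_dataset` list with elements `proteins` and
#'   `metabolites` ([omics_block]s on the raw intensity scale), `phenotype`,
#'   `fev1_fvc`, `covariates`, `signal_idx_1`, `signal_idx_2`, `latent`,
#'   `run_day_scale` and `config`.
#' @export
generate_multiomics <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  z <- stats::rnorm(n)
  C <- if (cfg$n_covariates > 0)
    matrix(stats::rnorm(n * cfg$n_covariates), n, cfg$n_covariates)
  else matrix(0, n, 0)
  colnames(C) <- if (ncol(C)) paste0("cov", seq_len(ncol(C))) else character(0)

  signal_idx_1 <- seq_len(cfg$n_signal_1)
  signal_idx_2 <- seq_len(cfg$n_signal_2)
  logP <- simulate_block_log(n, cfg$p_proteins, signal_idx_1, z, C, cfg)
  logM <- simulate_block_log(n, cfg$p_metabolites, signal_idx_2, z, C, cfg)

  pheno_cov <- if (cfg$n_covariates > 0)
    drop(C %*% stats::rnorm(cfg$n_covariates, sd = cfg$covariate_effect_sd))
  else 0
  phenotype <- cfg$phenotype_loading * z + pheno_cov +
    stats::rnorm(n, sd = cfg$noise_sd)

  ## ratio in (0, 1.2): logistic squash of a latent-driven score
  fev1_fvc <- 1.2 * stats::plogis(0.9 - 0.7 * z + stats::rnorm(n, sd = 0.4))

  run_day <- paste0("day", 1 + (seq_len(n) - 1L) %% cfg$n_run_days)
  day_scale <- exp(stats::rnorm(cfg$n_run_days, sd = cfg$run_day_scale_sd))
  names(day_scale) <- paste0("day", seq_len(cfg$n_run_days))

  P <- exp(logP)
  M <- exp(logM) * day_scale[run_day]
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(length(M)) < cfg$missing_rate, nrow(M), ncol(M))
    M[mask] <- NA_real_
  }

  subject_ids <- sprintf("S%04d", seq_len(n))
  proteins <- omics_block(P, subject_ids = subject_ids,
                          feature_ids = sprintf("prot%03d", seq_len(cfg$p_proteins)),
                          feature_kind = "protein")
  metabolites <- omics_block(M, subject_ids = subject_ids,
                             feature_ids = sprintf("met%03d", seq_len(cfg$p_metabolites)),
                             feature_kind = "metabolite", run_day = run_day)
  structure(list(proteins = proteins, metabolites = metabolites,
                 phenotype = phenotype, fev1_fvc = fev1_fvc,
                 covariates = C, signal_idx_1 = signal_idx_1,
                 signal_idx_2 = signal_idx_2, latent = z,
                 run_day_scale = day_scale, config = cfg),
            class = "synthetic_dataset")
}

#' Generate a clinical table for a synthetic dataset
#'
#' Maps the continuous phenotype monotonically onto a percent-predicted FEV1
#' range of 20-120 (rank-preserving linear map), carries the generated
#' FEV1/FVC ratio, and draws percent emphysema (log-normal, latent-driven,
#' always nonnegative) and binary heart-disease and exacerbation indicators
#' whose log-odds depend on the latent factor through
#' `config$indicator_effect`.
#'
#' @param dataset a `synthetic_dataset` from [generate_multiomics()].
#' @param config the [synthetic_config()] used to generate it.
#' @return a data.frame with columns `subject_id`, `fev1_pct`, `fev1_fvc`,
#'   `pct_emphysema`, `heart_disease`, `exacerbations`.
#' @export
generate_clinical_labels <- function(dataset, config = dataset$config) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  set.seed(substream_seed(config$seed, "clinical"))
  z <- dataset$latent
  ph <- dataset$phenotype
  rng <- range(ph)
  span <- if (diff(rng) > 0) diff(rng) else 1
  ## low phenotype = low lung function; monotone increasing map onto 20-120
  fev1_pct <- 20 + 100 * (ph - rng[1]) / span
  pct_emphysema <- exp(1.2 + 0.7 * (-z) + stats::rnorm(length(z), sd = 0.5))
  eff <- config$indicator_effect
  heart_disease <- as.integer(
    stats::runif(length(z)) < stats::plogis(-1.2 + eff * (-z)))
  exacerbations <- as.integer(
    stats::runif(length(z)) < stats::plogis(-0.8 + eff * (-z)))
  data.frame(subject_id = dataset$proteins$subject_ids,
             fev1_pct = fev1_pct, fev1_fvc = dataset$fev1_fvc,
             pct_emphysema = pct_emphysema, heart_disease = heart_disease,
             exacerbations = exacerbations, stringsAsFactors = FALSE)
}

#' Write a synthetic dataset as delimited text
#'
#' One file per omics block (with run-day column for metabolites), one
#' clinical table, and a ground-truth JSON recording the planted signal
#' indices, the loading interval and the seed.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if absent).
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(proteins = file.path(dir, "proteins.tsv"),
             metabolites = file.path(dir, "metabolites.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             covariates = file.path(dir, "covariates.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  write_omics_table(dataset$proteins, paths[["proteins"]])
  mdf <- data.frame(subject_id = dataset$metabolites$subject_ids,
                    run_day = dataset$metabolites$run_day,
                    as.data.frame(dataset$metabolites$values, check.names = FALSE),
                    check.names = FALSE)
  utils::write.table(mdf, paths[["metabolites"]], sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  clin <- generate_clinical_labels(dataset)
  clin$phenotype <- dataset$phenotype
  utils::write.table(clin, paths[["clinical"]], sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  cov <- data.frame(subject_id = dataset$proteins$subject_ids,
                    dataset$covariates, check.names = FALSE)
  utils::write.table(cov, paths[["covariates"]], sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  truth <- list(signal_idx_1 = dataset$signal_idx_1,
                signal_idx_2 = dataset$signal_idx_2,
                signal_ids_1 = dataset$proteins$feature_ids[dataset$signal_idx_1],
                signal_ids_2 = dataset$metabolites$feature_ids[dataset$signal_idx_2],
                latent_loading_range = dataset$config$latent_loading_range,
                phenotype_loading = dataset$config$phenotype_loading,
                seed = dataset$config$seed)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
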