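#' Extract candidate modules from a similarity matrix
#'
#' Hierarchical clustering on the dissimilarity `1 - similarity` with the
#' configured linkage; the tree is cut at `cut_height`. Clusters with at
#' least 2 features become modules; all remaining features form the
#' complement set. With a max-normalized similarity, a cut just below 1
#' groups any connected structure while isolated features fall into the
#' complement.
#'
#' @param sim a `similarity_matrix` from [build_similarity()].
#' @param cut_height tree cut height on the dissimilarity scale
#'   (default 0.999).
#' @param linkage linkage method passed to [stats::hclust()]
#'   (default "average").
#' @return a list: `modules` (list of integer index vectors into the
#'   concatenated feature set), `complement` (integer vector).
#' @export
extract_modules <- function(sim, cut_height = 0.999, linkage = "average") {
  stopifnot(inherits(sim, "similarity_matrix"))
  A <- sim$values
  p <- nrow(A)
  if (all(A == 0)) {
    warning("all-zero similarity: no modules")
    return(list(modules = list(), complement = seq_len(p)))
  }
  D <- stats::as.dist(1 - A)
  hc <- stats::hclust(D, method = linkage)
  labels <- stats::cutree(hc, h = cut_height)
  groups <- split(seq_len(p), labels)
  modules <- groups[vapply(groups, length, 1L) >= 2]
  ## drop within-module features with no positive similarity to the module
  modules <- lapply(modules, function(idx) {
    if (length(idx) < 2) return(idx)
    keep <- vapply(idx, function(i)
      any(A[i, setdiff(idx, i)] > 0), logical(1))
    idx[keep]
  })
  modules <- modules[vapply(modules, length, 1L) >= 2]
  names(modules) <- NULL
  in_module <- unlist(modules, use.names = FALSE)
  list(modules = modules,
       complement = setdiff(seq_len(p), in_module))
}

#' Trim a module's edges by similarity threshold
#'
#' Keeps within-module edges with similarity weight at least `tau`, drops
#' nodes left with degree 0, and records signed edges and node degrees.
#'
#' @param module integer index vector of module members (into the
#'   concatenated similarity feature set).
#' @param sim the source `similarity_matrix`.
#' @param tau nonnegative edge threshold.
#' @return a `trimmed_network` list: `nodes`, `node_ids`, `node_kind`,
#'   `edges` (data.frame from, to, weight, sign), `degrees`, `tau`,
#'   `n_protein`, `n_metabolite`.
#' @export
trim_edges <- function(module, sim, tau = 0) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (tau < 0) stop("tau must be >= 0")
  module <- sort(unique(as.integer(module)))
  if (length(module) < 2) stop("a module needs at least 2 features")
  A <- sim$values[module, module, drop = FALSE]
  Sg <- sim$signs[module, module, drop = FALSE]
  ut <- which(upper.tri(A) & A >= tau & A > 0, arr.ind = TRUE)
  if (nrow(ut) == 0)
    stop("edge threshold ", tau, " removes every edge (max available weight ",
         format(max(A[upper.tri(A)]), digits = 6), ")")
  edges <- data.frame(from = module[ut[, 1]], to = module[ut[, 2]],
                      weight = A[ut], sign = Sg[ut])
  deg_all <- table(factor(c(edges$from, edges$to), levels = module))
  keep <- module[deg_all > 0]
  edges <- edges[edges$from %in% keep & edges$to %in% keep, , drop = FALSE]
  degrees <- as.integer(table(factor(c(edges$from, edges$to), levels = keep)))
  names(degrees) <- sim$feature_ids[keep]
  kind <- sim$feature_kind[keep]
  structure(list(nodes = keep, node_ids = sim$feature_ids[keep],
                 node_kind = kind, edges = edges, degrees = degrees,
                 tau = tau,
                 n_protein = sum(kind == "protein"),
                 n_metabolite = sum(kind == "metabolite")),
            class = "trimmed_network")
}

#' @export
print.trimmed_network <- function(x, ...) {
  cat(sprintf("trimmed_network: %d nodes (%d protein, %d metabolite), %d edges, tau = %g\n",
              length(x$nodes), x$n_protein, x$n_metabolite, nrow(x$edges), x$tau))
  invisible(x)
}

#' Summarize a network by its first principal component
#'
#' PCA of the subjects x network-features submatrix; PC1 scores are the
#' subject-level network summary, correlated (Pearson) with the phenotype
#' over subjects with a non-missing phenotype. The two-sided p-value uses
#' the t transform `t = r sqrt(n-2) / sqrt(1-r^2)` on `n - 2` df. PC1 sign
#' is fixed so the largest-|loading| feature has a positive loading.
#'
#' @param net a `trimmed_network` (or an integer vector of feature indices).
#' @param X standardized combined omics matrix whose columns follow the
#'   similarity feature order.
#' @param phenotype numeric phenotype vector (missing allowed).
#' @return a `network_summary` list: `pc1` scores, `rho`, `p_value`,
#'   `n_used`, `variance_explained`, `loadings`.
#' @export
summarize_network <- function(net, X, phenotype) {
  idx <- if (inherits(net, "trimmed_network")) net$nodes else as.integer(net)
  if (length(idx) < 2) stop("need at least 2 network features")
  X <- as.matrix(X)
  sub <- X[, idx, drop = FALSE]
  pc <- stats::prcomp(sub, center = TRUE, scale. = FALSE)
  load1 <- pc$rotation[, 1]
  if (load1[which.max(abs(load1))] < 0) {
    load1 <- -load1
    pc$x[, 1] <- -pc$x[, 1]
  }
  scores <- pc$x[, 1]
  ok <- !is.na(phenotype)
  n_used <- sum(ok)
  if (n_used < 3) stop("fewer than 3 subjects with non-missing phenotype")
  rho <- stats::cor(scores[ok], phenotype[ok])
  p <- cor_pvalue(rho, n_used)
  ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
  structure(list(pc1 = scores, rho = rho, p_value = p, n_used = n_used,
                 variance_explained = ve, loadings = load1),
            class = "network_summary")
}

#' Per-node phenotype correlations
#'
#' One row per network node: feature id, kind, Pearson correlation with the
#' phenotype, two-sided p-value and degree, in the layout of a per-feature
#' network table.
#'
#' @inheritParams summarize_network
#' @return a data.frame with columns `feature_id`, `kind`, `r`, `p_value`,
#'   `degree`.
#' @export
node_correlations <- function(net, X, phenotype) {
  stopifnot(inherits(net, "trimmed_network"))
  X <- as.matrix(X)
  ok <- !is.na(phenotype)
  if (sum(ok) < 3) stop("fewer than 3 subjects with non-missing phenotype")
  r <- drop(stats::cor(X[ok, net$nodes, drop = FALSE], phenotype[ok]))
  data.frame(feature_id = net$node_ids, kind = net$node_kind, r = r,
             p_value = cor_pvalue(r, sum(ok)),
             degree = as.integer(net$degrees),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank network hubs by degree
#'
#' Nodes in descending degree order (ties broken by feature id), plus the
#' single maximum-weight edge of the network.
#'
#' @param net a `trimmed_network`.
#' @return a list: `ranking` (data.frame feature_id, kind, degree),
#'   `strongest_edge` (one-row data.frame with ids and weight).
#' @export
hub_report <- function(net) {
  stopifnot(inherits(net, "trimmed_network"))
  if (!nrow(net$edges)) stop("empty network")
  ord <- order(-as.integer(net$degrees), net$node_ids)
  ranking <- data.frame(feature_id = net$node_ids[ord],
                        kind = net$node_kind[ord],
                        degree = as.integer(net$degrees)[ord],
                        stringsAsFactors = FALSE)
  top <- which.max(net$edges$weight)
  pos <- match(c(net$edges$from[top], net$edges$to[top]), net$nodes)
  strongest <- data.frame(from = net$node_ids[pos[1]],
                          to = net$node_ids[pos[2]],
                          weight = net$edges$weight[top],
                          sign = net$edges$sign[top],
                          stringsAsFactors = FALSE)
  list(ranking = ranking, strongest_edge = strongest)
}

#' Sweep scaling constants and edge thresholds
#'
#' For each scaling constant `s`: builds the consensus similarity matrix,
#' extracts modules, and selects the module with the largest untrimmed
#' |PC1-phenotype correlation|; then, for each threshold `tau`, trims the
#' module and records a diagnostics row (|rho|, node count, protein to
#' metabolite ratio, edge count, edge-weight summary). The selected (s, tau)
#' maximizes |rho| subject to the acceptance rules: |rho| >= `min_rho`, both
#' feature kinds present, and protein:metabolite ratio inside `ratio_band`.
#' |rho| values within `rho_tol` of the accepted maximum count as tied
#' (network-phenotype correlations are conventionally reported to two
#' decimals, so differences below half that resolution are not
#' distinguishable); ties prefer the larger tau (sparser, stronger-edged
#' network), then the smaller s.
#'
#' @param X1,X2 standardized matrices; `y` phenotype (missing allowed,
#'   handled pairwise).
#' @param s_values scaling constants to sweep (default 5, 10, 15, 20).
#' @param tau_values edge thresholds (default 0 to 0.7 by 0.05).
#' @param l1,l2 sparsity fractions (typically from [cv_select_penalties()]).
#' @param fraction_1,fraction_2,n_subsamples subsampling scheme.
#' @param cut_height,linkage module extraction parameters.
#' @param min_rho minimum |PC1 correlation| to accept (default 0.20).
#' @param ratio_band acceptable protein:metabolite node-count ratio interval
#'   (default c(0.25, 4)).
#' @param rho_tol |rho| resolution for tie-breaking (default 0.005).
#' @param seed integer seed for the subsampling streams.
#' @return a `sweep_result` list: `table` (one diagnostics row per (s, tau)),
#'   `selected` (list s, tau, network, summary, similarity) or NULL when no
#'   configuration passes the rules.
#' @export
hyperparameter_sweep <- function(X1, X2, y, s_values = c(5, 10, 15, 20),
                                 tau_values = seq(0, 0.7, by = 0.05),
                                 l1 = 0.5, l2 = 0.5,
                                 fraction_1 = 0.7, fraction_2 = 0.7,
                                 n_subsamples = 100, cut_height = 0.999,
                                 linkage = "average", min_rho = 0.20,
                                 ratio_band = c(0.25, 4), rho_tol = 0.005,
                                 seed = 1L) {
  if (!length(s_values) || !length(tau_values)) stop("empty sweep grid")
  Xall <- cbind(as.matrix(X1), as.matrix(X2))
  rows <- list()
  cache <- list()
  for (s in sort(s_values)) {
    sim <- build_similarity(X1, X2, y, s = s, l1 = l1, l2 = l2,
                            fraction_1 = fraction_1, fraction_2 = fraction_2,
                            n_subsamples = n_subsamples,
                            seed = substream_seed(seed, paste0("sweep_s", s)))
    mods <- extract_modules(sim, cut_height = cut_height, linkage = linkage)
    if (!length(mods$modules)) next
    mod_rho <- vapply(mods$modules, function(m)
      abs(summarize_network(m, Xall, y)$rho), numeric(1))
    module <- mods$modules[[which.max(mod_rho)]]
    cache[[as.character(s)]] <- list(sim = sim, module = module,
                                     complement = mods$complement)
    for (tau in tau_values) {
      net <- tryCatch(trim_edges(module, sim, tau), error = function(e) NULL)
      if (is.null(net)) {
        rows[[length(rows) + 1]] <- data.frame(
          s = s, tau = tau, abs_rho = NA_real_, n_nodes = 0L,
          n_protein = 0L, n_metabolite = 0L, pm_ratio = NA_real_,
          n_edges = 0L, w_min = NA_real_, w_median = NA_real_,
          w_max = NA_real_, accepted = FALSE)
        next
      }
      summ <- summarize_network(net, Xall, y)
      ratio <- if (net$n_metabolite > 0 && net$n_protein > 0)
        net$n_protein / net$n_metabolite else NA_real_
      ok <- !is.na(ratio) && abs(summ$rho) >= min_rho &&
        ratio >= ratio_band[1] && ratio <= ratio_band[2]
      rows[[length(rows) + 1]] <- data.frame(
        s = s, tau = tau, abs_rho = abs(summ$rho),
        n_nodes = length(net$nodes), n_protein = net$n_protein,
        n_metabolite = net$n_metabolite, pm_ratio = ratio,
        n_edges = nrow(net$edges), w_min = min(net$edges$weight),
        w_median = stats::median(net$edges$weight),
        w_max = max(net$edges$weight), accepted = ok)
    }
  }
  tab <- do.call(rbind, rows)
  best <- NULL
  acc <- which(tab$accepted)
  if (length(acc)) {
    top <- max(tab$abs_rho[acc])
    tied <- acc[tab$abs_rho[acc] >= top - rho_tol]
    pick <- tied[order(-tab$tau[tied], tab$s[tied])][1]
    s_sel <- tab$s[pick]
    tau_sel <- tab$tau[pick]
    cc <- cache[[as.character(s_sel)]]
    net <- trim_edges(cc$module, cc$sim, tau_sel)
    best <- list(s = s_sel, tau = tau_sel, abs_rho = tab$abs_rho[pick],
                 network = net, summary = summarize_network(net, Xall, y),
                 similarity = cc$sim, complement = cc$complement)
  } else {
    warning("no (s, tau) configuration passed the acceptance rules")
  }
  structure(list(table = tab, selected = best), class = "sweep_result")
}
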