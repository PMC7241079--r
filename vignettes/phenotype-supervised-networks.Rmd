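---
title: "Phenotype-supervised protein-metabolite networks with sparse multiple CCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-supervised protein-metabolite networks with sparse multiple CCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

# The problem

Blood proteomics and metabolomics each carry partial information about a
clinical phenotype such as lung function (percent-predicted FEV1) or CT
percent emphysema. Single-feature screens miss coordinated multi-omic
structure; unsupervised integration finds inter-omics correlation that may
be irrelevant to the phenotype. `pmnet` implements a supervised middle
ground: sparse multiple canonical correlation analysis (SmCCA) finds sparse
linear combinations of proteins and of metabolites that co-vary with each
other *and* with the phenotype, and the resulting canonical weights induce a
feature-feature network whose modules are candidate phenotype-associated
protein-metabolite subnetworks.

# The model

Let $X_1$ ($n \times p_1$ proteins) and $X_2$ ($n \times p_2$ metabolites)
be column-standardized and $y$ the standardized phenotype. With
$\Sigma_{12} = X_1^\top X_2/(n-1)$ and
$\sigma_{ky} = X_k^\top y/(n-1)$ (all entries Pearson correlations), the
weighted objective is

$$
J(w_1, w_2) \;=\; w_1^\top \Sigma_{12} w_2
  \;+\; s\,\bigl(w_1^\top \sigma_{1y} + w_2^\top \sigma_{2y}\bigr),
\qquad
\lVert w_k\rVert_2 \le 1,\;
\lVert w_k\rVert_1 \le l_k\sqrt{p_k}.
$$

The phenotype is treated as a fixed scalar third block with weight $+1$, so
only the two omics weight vectors are optimized. The scaling constant
$s \ge 0$ prioritizes omics-phenotype over omics-omics correlation; it
matters whenever the inter-omics correlation range is wider than the
omics-phenotype range (the `correlation_range_report()` diagnostic flags
exactly this situation, which is typical: thousands of co-regulated
features correlate with each other far more strongly than any of them
correlates with a clinical phenotype).

`fit_smcca()` solves the problem by block coordinate ascent. Each block
update is a linear maximization over the intersection of the L2 ball and
the L1 ball, solved in closed form by soft-thresholding followed by L2
normalization, with the threshold found by bisection (`project_l1_l2()`).
Because each half-step exactly maximizes $J$ in one block given the other,
the objective sequence is non-decreasing — this is asserted at every
iteration. Iteration stops when the largest weight change falls below
`tol = 1e-6` (cap `max_iter = 200`).

Numerical choices worth knowing:

* **Initialization** is deterministic: $w_2 \propto$ column sums of
  $|\Sigma_{12}|$ (each entry aggregates a block-2 feature's total
  cross-block association). No random restarts, hence no run-to-run
  variance.
* **Penalty parameterization**: the printed grid values $l_k \in (0, 1]$
  scale the L1 budget as $l_k\sqrt{p_k}$, so $l = 1$ is the unpenalized
  limit for any block size. For small blocks the budget is clamped below
  at 1 because a unit-L2 vector cannot have L1 norm under 1; at the clamp
  the fit selects a single feature. `project_l1_l2()` itself rejects
  budgets below 1.
* **Tie-breaking** is by lowest index everywhere (one-hot corner of the
  projection, module choice, hub ranking).

# Penalty selection

`cv_select_penalties()` evaluates every pair from the grid
$(0.05, 0.15, 0.25, 0.35, 0.45, 0.55)$ — 36 pairs — by repeated 5-fold
cross-validation (5 independent fold partitions by default). Training and
held-out splits are standardized independently; the trained weights are
scored by the weighted objective on the held-out split, and the chosen pair
maximizes the mean held-out objective.

This criterion is a deliberate design choice. The more obvious "train
minus test objective gap" (absolute or relative) measures only overfit,
and its minimum is flat across support sizes: a single-feature fit
generalizes essentially perfectly, so fold noise decides between a
one-feature and a forty-feature support. On synthetic data with planted
signal, gap-based selection collapses to near-one-hot supports on a
substantial fraction of generator seeds, destroying downstream module
recovery. The held-out objective instead rewards supports that carry
genuine, generalizing association: it increases while added features
contribute signal and flattens once they add noise, and it selects the
same interior grid point across every generator seed we simulate.
Repeating the fold partition five times averages away most of the
remaining partition noise.

# From weights to a network

Sparse weights from a single fit are unstable in the same way any sparse
selector is. `build_similarity()` therefore averages over feature
subsampling: in each of `n_subsamples = 100` replicates, 70% of each
block's features are drawn without replacement, SmCCA is fitted on the
subsample, the weights are embedded into full-length vectors, and
$|\tilde w \tilde w^\top|$ is accumulated. The average is normalized by its
maximum off-diagonal entry, giving a similarity matrix in $[0, 1]$ with
zero diagonal; edge signs come from the full-data Pearson correlations.
The subsampling fraction and replicate count are exposed configuration;
0.7 and 100 keep desk-scale runtime while giving every feature frequent
chances to compete.

Modules are extracted by average-linkage hierarchical clustering on
$1 - \text{similarity}$ with the tree cut at 0.999
(`extract_modules()`). Because the similarity is max-normalized, a cut
just below 1 groups any features with non-negligible consensus
association while isolated features fall into the complement set.
Clusters of size two or more are modules; the module whose untrimmed PC1
best correlates with the phenotype is carried forward.

`trim_edges()` applies an edge threshold $\tau$, dropping edges below
$\tau$ and then nodes of degree zero. `summarize_network()` scores
subjects by the first principal component of the network's feature
submatrix (PC1 — the direction of maximal shared variance, the standard
module summary), fixes the PC1 sign so the largest-|loading| feature loads
positively, and reports the Pearson correlation $\rho$ of PC1 with the
phenotype together with a two-sided p-value from
$t = r\sqrt{n-2}/\sqrt{1-r^2}$. Because the sign convention is internal,
reported $\rho$ may differ in sign from other analyses of the same data.

# Hyperparameter sweep

`hyperparameter_sweep()` scans scaling constants (default $5, 10, 15,
20$) and edge thresholds ($0$ to $0.7$ by $0.05$), recording per
configuration: $|\rho|$, node count, protein:metabolite ratio, edge count
and edge-weight summary. A configuration is *accepted* when
$|\rho| \ge 0.20$, both feature kinds are present, and the
protein:metabolite ratio lies in $[0.25, 4]$ (a formalization of "near
equal proportions"). Among accepted configurations the selection maximizes
$|\rho|$, with values within `rho_tol = 0.005` of the maximum treated as
tied — network-phenotype correlations are conventionally reported to two
decimals, so differences below half that resolution are not meaningful —
and ties resolved toward the larger $\tau$ (sparser, stronger-edged
network), then the smaller $s$. The $|\rho|$ surface is typically a
plateau once the core signal features are in the network, so the tie rule,
not the maximum itself, usually determines the final network; preferring
the sparser end of the plateau yields the trimmed, interpretable networks
the method aims for.

# Preprocessing

The metabolomics chain runs in a fixed order, each step motivated by a
specific artifact of untargeted MS data:

1. **Run-day normalization**: each feature is divided by its run-day
   median and rescaled by its overall median (medians over observed values
   only), exactly correcting a per-day multiplicative batch factor.
2. **Outlier subjects**: features are z-scored; subjects whose median
   feature z-score lies more than 3.5 SD from the cohort mean of those
   aggregates are removed. (The aggregate is the median of feature
   z-scores per subject; the alternative reading — z-score of the subject
   median — is less robust to a handful of extreme features.)
3. **Missingness filter**: features missing in strictly more than 20% of
   subjects are dropped (strict inequality, as printed conventions state).
4. **KNN imputation** (k = 10) across features on the raw scale: a missing
   cell takes the mean of the k nearest features (Euclidean distance over
   co-observed subjects) that are observed for that subject. Imputation
   precedes the log transform, matching the stated processing order.
5. **Log + standardization**: natural log, then per-column center/scale
   with the $n-1$ denominator.
6. **Covariate residualization** (adjusted branch only): each feature is
   replaced by its OLS residual on an intercept plus blood-cell
   covariates, then re-standardized. Re-standardization is our choice —
   canonical correlation is scale-invariant but the similarity
   normalization is not, so adjusted and unadjusted branches must feed
   identically scaled inputs.

Proteomics inputs are assumed vendor-normalized; only log +
standardization (and optional residualization) is applied. Missing
phenotype values are never imputed; subjects are dropped pairwise per
analysis.

# Evaluation components

* **Sensitivity comparison**: adjusted and unadjusted node sets are
  compared by a one-sided Fisher's exact test for overlap enrichment over
  the universe of all features that entered the analysis after filtering
  (only those could have appeared in either network); the sample odds
  ratio $ad/bc$ is reported. One-sidedness is our choice: enrichment is
  the directional question asked of the overlap.
* **Per-feature screening**: two-sided correlation p-values
  (t-transform), Benjamini-Hochberg adjusted; a feature is significant
  only when both $|r| > 0.15$ and adjusted $p < 0.001$.
* **Clinical grading**: GOLD 0-4 and PRISm from percent-predicted FEV1
  and FEV1/FVC at the conventional thresholds (80/50/30% and 0.7);
  emphysema severity bins are $[0,5)$, $[5,10)$, $[10,20]$,
  $(20,\infty)$ — 20 belongs to "moderate" so "severe" is strictly
  above 20%, and the interior boundaries are assigned upward to make the
  bins a partition.
* **Subgroup analysis**: one-way ANOVA of network PC1 across cohort
  subgroups followed by Tukey's HSD (studentized-range adjusted pairwise
  p-values); with two groups the comparison coincides with the pooled
  t-test.

# The synthetic generator

`generate_multiomics()` emulates the statistical structure the analysis
assumes: a standard-normal latent factor $z$ per subject; signal features
with log-intensity $\beta_j z$ plus linear effects of 6 standard-normal
covariates plus Gaussian noise; non-signal features without the latent
term; a phenotype $\gamma z$ + covariate contribution + noise;
exponentiation to a positive log-normal intensity scale; a per-day
multiplicative run-day factor on metabolites; and metabolite cells masked
missing completely at random. MCAR is the simplest mechanism consistent
with a missingness-fraction filter; real untargeted MS missingness is
partly intensity-dependent, which the generator does not model. Nor does
it model heavy-tailed intensity distributions, correlated noise within
pathways, or feature-dependent batch effects — so passing recovery tests
demonstrates correctness of the pipeline's logic under its own
assumptions, not performance guarantees on real cohort data.

Clinical labels derive monotonically from the same latent structure:
percent-predicted FEV1 is a rank-preserving linear map of the phenotype
onto 20-120; FEV1/FVC is a logistic squash into $(0, 1.2)$; percent
emphysema is log-normal and latent-driven; binary heart-disease and
exacerbation indicators follow logistic models with a configurable latent
effect.

Generator defaults define the reference validation conditions used
throughout the tests: $n = 500$ subjects, $60 + 60$ features, $10 + 10$
planted signal features, unit loadings, noise SD 0.5 for recovery runs
(1.0 as the general default), 5% missingness, 4 run days with log-scale
batch SD 0.2, covariate effect SD 0.3. Effect sizes in the motivating
cohort are unknown; these values are chosen to make recovery a meaningful
but non-trivial test (module PC1-phenotype correlations land around
0.6-0.8, comfortably above the 0.20 acceptance rule but far from
noiseless).

# Problem sizes and determinism

The test suite and the acceptance script run the full pipeline at the
reference size above (a few seconds per run), solver cross-checks against
an SVD closed form and a multi-start quasi-Newton maximizer at $p \le 6$,
and oracle enumerations (hypergeometric tails, studentized-range Monte
Carlo, brute-force projections) at sizes where exhaustive computation is
exact or Monte-Carlo error is controlled. All randomness flows from a
single seed through named substreams per stage, so identical
configurations reproduce byte-identical manifests.

# Known limitations

* Exactly two omics blocks and a single continuous phenotype; no
  categorical phenotypes.
* The phenotype scaling constant enters both omics-phenotype terms with a
  single value $s$, consistent with analyses that report one scaling
  constant; per-block constants are not supported.
* Module extraction depends on the max-normalized similarity scale; a
  single dominating edge compresses all other similarities, which the
  edge-threshold sweep partly compensates.
* The CV criterion targets generalizing association strength, not support
  recovery per se; with very weak signal the selected penalties can still
  under- or over-select.
* P-values for PC1-phenotype correlations do not account for the
  data-driven selection of the network (selective inference is out of
  scope); they match the conventional reporting practice for module
  summaries.
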