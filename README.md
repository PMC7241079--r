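# pmnet — phenotype-supervised protein–metabolite networks

`pmnet` discovers protein–metabolite networks associated with a continuous
clinical phenotype (e.g. percent-predicted FEV1 or CT percent emphysema)
by integrating a proteomic matrix, a metabolomic matrix and the phenotype
with **sparse multiple canonical correlation analysis (SmCCA)**. It is
aimed at analysts of paired blood multi-omics in clinical cohorts who want
interpretable, phenotype-relevant feature networks rather than
single-feature association lists.

## The method

With standardized blocks `X1` (n × p1), `X2` (n × p2) and phenotype `y`,
SmCCA maximizes

    J(w1, w2) = w1' Σ12 w2 + s (w1' σ1y + w2' σ2y),
        ||wk||2 ≤ 1,  ||wk||1 ≤ lk √pk

where `Σ12` and `σky` contain Pearson correlations, `s` is a scaling
constant that prioritizes phenotype association over inter-omics
correlation, and `lk` are sparsity fractions chosen by repeated 5-fold
cross-validation over the grid (0.05, …, 0.55). The solver is block
coordinate ascent with an exact L1/L2 projection step (soft-threshold +
bisection); its objective is provably non-decreasing.

Sparse weights are stabilized by feature subsampling: SmCCA is refitted on
random 70% feature subsets and `|w w'|` is averaged into a consensus
similarity matrix. Hierarchical clustering extracts modules; an edge
threshold `τ` trims weak edges; the surviving network is summarized by the
first principal component (PC1) of its feature submatrix and the Pearson
correlation of PC1 with the phenotype. A sweep over `(s, τ)` produces a
diagnostics table (|rho|, node counts, protein:metabolite ratio, edge
strength) and a final selection under acceptance rules (|rho| ≥ 0.20, both
feature kinds present, near-balanced composition).

Around this core the package implements metabolomics preprocessing
(run-day median normalization, 3.5-SD aggregate outlier removal, >20%
missingness filter, feature-wise KNN imputation with k = 10, log +
standardization), covariate residualization for adjusted/unadjusted
sensitivity analysis with a Fisher's-exact node-overlap comparison,
BH-FDR per-feature screening (|r| > 0.15 and adjusted p < 0.001),
GOLD/PRISm and emphysema-severity grading, subgroup ANOVA + Tukey HSD on
network PC1, and a seeded synthetic generator with planted latent signal
for end-to-end validation. Networks export as SIF and GraphML for
Cytoscape-class tools.

## Worked example

Generate a synthetic cohort with planted signal (10 of 60 proteins and 10
of 60 metabolites driven by one latent factor that also drives the
phenotype), then run the full pipeline on the covariate-adjusted branch:

```r
library(pmnet)

cfg <- synthetic_config(n_subjects = 500, p_proteins = 60, p_metabolites = 60,
                        n_signal_1 = 10, n_signal_2 = 10,
                        latent_loading_range = c(1, 1), noise_sd = 0.5,
                        missing_rate = 0.05, seed = 7)
rc  <- run_config(synthetic = cfg, adjustment = "adjusted",
                  out_dir = file.path(tempdir(), "demo"), seed = 7)
res <- run_pipeline(rc)

b <- res$branches$adjusted
b$cv$chosen                      # penalties chosen by repeated 5-fold CV
res$branches$adjusted$network    # the selected trimmed network
b$summary$rho                    # PC1-phenotype correlation
```

Output:

```
chosen penalties: l1 = 0.45, l2 = 0.45
selected scaling s = 5, edge threshold tau = 0.70
trimmed_network: 20 nodes (10 protein, 10 metabolite), 126 edges, tau = 0.7
PC1-phenotype rho = 0.759 (p = 8.87e-95, n = 499)
complement |rho| = 0.010
 feature_id       kind         r      p_value degree
    prot010    protein 0.6883169 2.659813e-71     18
    prot006    protein 0.6865508 8.371228e-71      9
    prot007    protein 0.6863792 9.354007e-71     13
     met004 metabolite 0.6833313 6.628955e-70     18
    prot008    protein 0.6833083 6.727100e-70     15
```

The selected network recovers exactly the 20 planted signal features (10
proteins + 10 metabolites, zero contamination). Its PC1 correlates with
the phenotype at |rho| = 0.76, while the PC1 of all features *not* in the
network correlates at only 0.01 — the contrast that distinguishes a
phenotype-driven module from background. Per-node correlations and degrees
(the node table above) identify hubs; `write_network()` has already
exported SIF/GraphML files plus a node-attribute table under the run's
output directory, alongside a JSON manifest recording seeds, chosen
hyperparameters and stage-by-stage dimensions.

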