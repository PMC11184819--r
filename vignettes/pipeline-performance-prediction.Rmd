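---
title: "Predicting dataset-specific scRNA-seq clustering pipeline performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting dataset-specific scRNA-seq clustering pipeline performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A single-cell RNA-seq clustering analysis is a composition of choices:
how to filter low-quality cells, how to normalize counts, how many
principal components to keep, and at what resolution to cluster the
neighbor graph. Even a modest menu of options multiplies into hundreds of
distinct pipelines — here, 3 filtering strategies x 3 normalizations x
4 dimensionalities x 8 resolutions = 288 — and benchmarking studies
consistently find that no single pipeline wins on every dataset. `scperf`
treats this as a prediction problem: run many pipelines over many
datasets, score every clustering with unsupervised quality metrics, and
train supervised *meta-models* that predict, for an unseen dataset, how
well each pipeline will do — using only the pipeline's parameters and
cheap, label-free characteristics of the dataset.

Because the package is driven entirely by synthetic data, the whole study
is reproducible on a laptop with no downloads: a negative-binomial
generator stands in for real dataset collections, and planted-signal
performance tables provide ground truth for validating the meta-learning
machinery itself.

```{r, eval = FALSE}
library(scperf)
bundle <- run_full_study(seed = 1, verbose = TRUE)
bundle$significance
```

# The synthetic data generator

Counts for cell $c$ in cluster $k$ are drawn as
$x_{gc} \sim \mathrm{NB}(\mu = \ell_c\, p_{gk},\ \theta)$, the
gamma-Poisson mixture that is the de-facto standard model for scRNA-seq
counts. The pieces:

* a log-normal baseline expression profile over genes, shared by all
  clusters;
* per-cluster log2 fold changes planted on a `de_prob` fraction of genes
  with standard deviation `logfc_sd` — these are what make clusters
  separable;
* log-normal library sizes $\ell_c$ (`libsize_mu_log`, `libsize_sd_log`);
* NB dispersion $\theta$ (`nb_dispersion`): variance is
  $\mu + \mu^2/\theta$, so $\theta \to \infty$ recovers Poisson;
* a small fraction of *outlier cells* whose mitochondrial genes are
  re-weighted to ~35% of the library, far above the 8% QC threshold,
  so the filtering rules have realistic targets.

No zero inflation is added: NB sparsity at realistic depths is
sufficient. Batch effects, doublets and ambient RNA are deliberately out
of scope, so passing tests demonstrate that the pipeline and metric
machinery behaves correctly, not that it is robust to every artifact of
real data.

A *collection* draws per-dataset parameters uniformly within ranges
(`default_collection_ranges()`): 200–1500 cells, 2–8 clusters,
2000–8000 median counts/cell, dispersion 0.5–5, DE fraction 0.05–0.3.
These were chosen once as a caricature of a heterogeneous public atlas
collection — a few hundred to a couple thousand cells per study with
widely varying depth and population structure. All datasets in a
collection share one gene universe (ids and mito/coding flags) so the
dataset-by-gene mean-expression matrix needs no gene matching.

# The pipeline grid

`enumerate_grid()` builds the Cartesian product in a fixed order
(filtering slowest, resolution fastest) with stable `P%03d` ids. The
default levels give 288 configurations. The four steps:

1. **Filtering** — per-cell QC metrics via `scuttle::perCellQCMetrics`
   plus `featcount_dist`, the residual of log10 detected features
   regressed on log10 total counts (tricube-weighted, degree-2 local
   regression, span 0.75). MAD-rule outlier flags use the 1.4826
   consistency constant. *default* removes cells with ≥ 2 flags, where
   the count/feature flags are asymmetric (below median − 5 MADs or
   above median + 2.5 MADs — lenient at the low end, strict at the high
   end), top-20% and `featcount_dist` flags are two-sided at 5 MADs, and
   the mitochondrial flag requires both > median + 2.5 MADs and > 0.08;
   *stringent* removes on ≥ 1 of the same flags; *lenient* uses
   two-sided 5-MAD flags with the mitochondrial rule
   (> median + 3 MADs or > 0.08) and removes on ≥ 2. The mitochondrial
   threshold is a proportion (0.08 = 8%); top-N percentages live on the
   0–100 scale.
2. **Normalization** — `lognorm` is
   $\log(1 + 10^4 x/\ell)$; `pooling` is a simplified
   pooling-deconvolution (cells ordered by library size, overlapping
   ring pools, pooled median-ratio factors, per-cell factors by least
   squares; two coprime ring sizes are used because a single
   consecutive-ones circulant design is singular whenever the ring
   length shares a factor with the cell count); `pearson` computes
   analytic Pearson residuals under an NB null with fixed
   $\theta = 100$, clipped at $\pm\sqrt{n_\text{cells}}$. The latter
   two are deliberate desk-scale stand-ins that preserve the three-way
   methodological contrast rather than numerical replicas of the
   original tools.
3. **Dimensionality reduction** — genes centered and unit-scaled, top
   PCs by SVD, with the sign convention that each component's
   largest-magnitude loading is positive. HVG selection beforehand is
   vst-style: a local regression of log10 variance on log10 mean gives a
   predicted standard deviation per gene; counts are standardized and
   clipped at $\sqrt{n_\text{cells}}$, and genes are ranked by the
   variance of the standardized values (top 2000 by default, ties broken
   by gene order). For Pearson-residual normalization, HVGs are ranked
   on the raw counts, since residuals destroy the mean-variance trend
   the ranking relies on.
4. **Clustering** — a k = 20 nearest-neighbor graph, Jaccard
   re-weighting of edges by neighbor-set overlap, pruning below 1/15,
   then Louvain modularity optimization at the grid resolution with a
   fixed seed. Neighbor count and pruning follow the conventions of the
   popular toolchain; they are not tunable per pipeline.

`run_pipeline()` composes the steps; `run_grid()` sweeps dataset x
configuration, captures per-run failures as error records without
aborting, and caches on (dataset, pipeline) keys so reruns are
idempotent. One pragmatic deviation: `run_pipeline()` caps the number of
PCs at what the post-filtering cell and HVG counts allow instead of
failing, so small datasets still traverse the grid; `reduce_dims()`
itself errors on an infeasible request.

# Scoring clusterings

Four metrics per clustering, all oriented so higher is better:

* **CH** (Calinski-Harabasz): $[B/(k-1)]/[W/(n-k)]$;
* **DB$_{neg}$**: $-1 \times$ Davies-Bouldin, negated so its
  orientation matches the others;
* **SIL**: mean silhouette, with singleton-cluster points scored 0;
* **GSEA**: per cluster, genes are ranked by one-vs-rest log2 fold
  change of mean expression (pseudocount 1, ties broken by gene id), a
  classic weighted Kolmogorov-Smirnov enrichment score is computed per
  gene set, normalized by the mean absolute same-sign score over
  gene-label permutations (NES), and $|{\rm NES}|$ is averaged over
  size-filtered sets (strictly more than 10 and fewer than 500 genes)
  and then over clusters.

Purity metrics are computed on the log1p raw counts of the kept cells
restricted to the 500 most variable genes, with Euclidean distances
throughout. Permutation seeds for the GSEA metric are derived per gene
set and shared across clusters, which makes the metric exactly invariant
to cluster relabeling. The default permutation count is 1000; the
package's own tests and the end-to-end study use 100–200, which is
enough for a metric that is averaged over sets and clusters.

Three post-processing steps make metrics comparable across datasets and
honest across resolutions:

1. **Within-dataset scaling** to mean 0, variance 1 (sample sd), since
   raw metric scales are dominated by dataset-specific factors.
2. **k-correction**: purity metrics vary systematically with the number
   of clusters, which the resolution parameter controls almost directly
   — left uncorrected, a pipeline could "win" simply by choosing the k
   the metric likes. Per dataset, a local regression (tricube, degree 2,
   span 0.75) of the scaled metric on k is fitted and its residuals
   become the corrected metric. By default the GSEA score is scaled but
   not k-corrected (`correct_gsea = TRUE` opts in), mirroring the
   convention that only the cluster purity metrics need the k
   adjustment.
3. **Imputation**: single-cluster outputs leave metrics undefined; they
   are filled with the per-dataset median of the corrected value and
   flagged, after correction, so imputed rows sit at a neutral rank.

Scaling precedes correction; with z-scored inputs the loess residuals
are directly comparable across datasets, and correcting first would
reintroduce dataset scale into the trend fit.

# Dataset features and meta-models

Each dataset is summarized by **41 features**: 21 QC statistics (medians
of the per-cell metrics, MADs of counts/features, library-size CV and
skewness, sparsity, high-mito-cell fraction, coding fractions, cell and
gene counts — `dataset_qc_feature_names()` lists them) plus 20
probabilistic-PCA scores of the dataset-by-gene mean-expression matrix.
PPCA uses the closed-form maximum-likelihood solution (no EM, for
determinism): $\sigma^2$ is the mean of the discarded covariance
eigenvalues and $W = U_q(\Lambda_q - \sigma^2 I)^{1/2}$; held-out rows
are projected by the posterior mean
$(W^\top W + \sigma^2 I)^{-1}W^\top(x - \mu)$. The mean-expression
matrix enters PPCA untransformed (means of raw counts); a log1p option
exists but is off by default. Crucially, PPCA and the feature scaling
are fitted on the *training* datasets only and applied to the test
datasets — a leakage test asserts the stored train model is reused.

Meta-model rows are (dataset, pipeline) pairs; the target is the
corrected metric. Two feature modes: *pipeline-only* (4 pipeline
parameters — categorical steps as integer codes for trees, one-hot for
linear models) and *interactions* (41 dataset features + pipeline
parameters = 45 columns for trees, which learn interactions implicitly;
for linear models all 41 x 8 dataset x pipeline products are appended to
the mains, 377 columns). Resampling is *dataset-aware* everywhere: a
70/30 split forces label-bearing datasets into the test set, and 10-fold
CV partitions training datasets so no dataset ever straddles folds —
otherwise "test" performance would amount to having seen the dataset's
own benchmark results.

Tuning grids: random forest over ntree {100, 300, 500} and an mtry
subgrid {1, p/3, p/2, p} (the full 1..p sweep is possible but a subgrid
keeps desk-scale runtime; importances are IncNodePurity); elastic net
over alpha {0.10, 0.55, 1.00} and lambda {0.001, 0.01, 0.1} — the
original tooling derives data-dependent lambdas that are not
recoverable, so a fixed log-spaced grid is used. Selection minimizes the
dataset-aware cross-validated RMSE.

# Evaluation

Per test dataset, the Pearson correlation between predictions and
observed corrected metric values across pipelines; per model block, a
one-sided Wilcoxon signed-rank test of those correlations against zero
with Benjamini-Hochberg correction across blocks. (A rank-sum test needs
two samples; applied to a single sample of correlations, the signed-rank
test is the coherent reading, and `stats::wilcox.test` provides exactly
the exact-small-sample/normal-approximation behavior required.) On
labeled datasets the observed metric is replaced by the ARI between each
pipeline's clustering and the reference labels. Finally, dataset
features are correlated with per-dataset predictive performance
(two-sided correlation t-test), and features significant in at least one
block are reported — the "which datasets should trust these
recommendations" analysis.

# Validating the meta-learning machinery with planted tables

Real pipeline runs cannot tell you whether the *meta-learning* layer
works, because their ground truth is unknown. `planted_performance_model()`
therefore generates performance tables with a known bilinear structure
$y_{dp} = x_d^\top\beta_D + z_p^\top\beta_P + x_d^\top B z_p + \epsilon$:
with $B \ne 0$ the best pipeline is dataset-specific by construction.
The package's acceptance checks fit both feature modes on such tables
(40 datasets x 288 pipelines, noise sd at half the signal sd) and
require the interaction mode to win in median per-dataset test
correlation. This recovery check uses the elastic net with explicit
interaction terms: the planted surface lies exactly in that model class,
so the check isolates the meta-learning plumbing rather than a tree
ensemble's ability to approximate smooth bilinear functions from a few
dozen datasets (random-forest recovery of planted threshold structure is
exercised separately in the unit tests).

# Numerical choices and degenerate inputs

* MAD = 0 (identical QC values) produces no outlier flags; zero-total
  cells are always flagged and removed.
* Zero-variance metric blocks scale to 0 with a warning; constant-k
  datasets fall back to centering in the k-correction; loess falls back
  to linear fits when k takes fewer than 4 distinct values.
* `silhouette` of singleton clusters is 0; CH with $W = 0$ is `+Inf`;
  coincident DB centroids yield the undefined marker (`NA`), as does any
  metric at k = 1.
* GSEA sets with no overlap, or with no same-sign permutation scores,
  yield `NA` and are dropped from the within-cluster average.
* All stochastic stages take explicit integer seeds; a master seed is
  split with `split_seed()` (children < 2^30), and the Louvain heuristic
  runs under a fixed seed, so every result in the package is exactly
  reproducible.

# Problem sizes

The end-to-end study defaults (`default_study_config()`) are sized for a
single CPU: 6 datasets of 200–400 cells x 1200 genes, a 36-pipeline
subgrid (3 x 3 x 2 x 2), 15 gene sets at 100 permutations, and both
model kinds in both modes over all four metrics (16 blocks), completing
in a few minutes and byte-identically under a fixed seed. These sizes
are package defaults chosen for interactive use; every one of them
scales up by argument.

# Known limitations

* The synthetic generator omits batch structure, doublets and ambient
  contamination; conclusions about robustness to those artifacts require
  real data.
* The pooling and Pearson-residual normalizations are simplified
  stand-ins, not numerical replicas of the original implementations.
* With 6-dataset default studies the test set holds 2 datasets, so the
  signed-rank significance machinery (which needs ≥ 5 correlations)
  reports `NA` at that scale; planted-table checks cover it at 40
  datasets.
* Gene-set enrichment uses synthetic identifiers directly; no
  symbol mapping or FDR filtering of sets is performed.
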