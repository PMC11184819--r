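#' Configuration for one synthetic scRNA-seq dataset
#'
#' Parameters of the gamma-Poisson (negative binomial) cluster-mixture
#' generator.  Counts for cell \eqn{c} in cluster \eqn{k} are drawn as
#' \eqn{x_{gc} \sim NB(\mu = \ell_c p_{gk}, \theta)} where the cluster
#' expression profiles \eqn{p_{\cdot k}} differ by planted log2 fold changes
#' on a `de_prob` fraction of genes and \eqn{\ell_c} is a log-normal library
#' size.
#'
#' @param n_cells,n_genes,n_clusters dimensions of the dataset; `n_clusters`
#'   is the true number of cell populations (K).
#' @param cluster_props mixing proportions over the K clusters (must sum
#'   to 1); default uniform.
#' @param de_prob per-cluster probability that a gene is differentially
#'   expressed.
#' @param logfc_sd standard deviation of planted log2 fold changes.
#' @param libsize_mu_log,libsize_sd_log meanlog / sdlog of the log-normal
#'   library-size distribution (defaults give a median depth of ~5000
#'   counts per cell).
#' @param nb_dispersion negative-binomial size parameter \eqn{\theta > 0};
#'   larger values approach Poisson.
#' @param mito_frac fraction of genes flagged mitochondrial.
#' @param coding_frac fraction of genes flagged protein-coding.
#' @param outlier_cell_frac fraction of cells with inflated mitochondrial
#'   content (targets for QC filtering).
#' @param seed integer seed making the dataset reproducible.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_cells = 500, n_genes = 2000, n_clusters = 4,
                         cluster_props = NULL, de_prob = 0.1, logfc_sd = 1,
                         libsize_mu_log = log(5000), libsize_sd_log = 0.35,
                         nb_dispersion = 2, mito_frac = 0.05,
                         coding_frac = 0.8, outlier_cell_frac = 0.02,
                         seed = 1L) {
  if (is.null(cluster_props))
    cluster_props <- rep(1 / n_clusters, n_clusters)
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              n_clusters = as.integer(n_clusters),
              cluster_props = cluster_props, de_prob = de_prob,
              logfc_sd = logfc_sd, libsize_mu_log = libsize_mu_log,
              libsize_sd_log = libsize_sd_log,
              nb_dispersion = nb_dispersion, mito_frac = mito_frac,
              coding_frac = coding_frac,
              outlier_cell_frac = outlier_cell_frac, seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    if (n_cells < 1 || n_genes < 1 || n_clusters < 1)
      stop_scperf("n_cells, n_genes and n_clusters must be positive")
    if (n_clusters > n_cells)
      stop_scperf("invalid config: more clusters than cells (K > n_cells)")
    if (length(cluster_props) != n_clusters)
      stop_scperf("cluster_props must have length n_clusters")
    if (abs(sum(cluster_props) - 1) > 1e-9 || any(cluster_props < 0))
      stop_scperf("cluster_props must be non-negative and sum to 1")
    if (nb_dispersion <= 0)
      stop_scperf("nb_dispersion (theta) must be > 0")
  })
  for (f in c("de_prob", "mito_frac", "coding_frac", "outlier_cell_frac"))
    assert_fraction(cfg[[f]], f)
  invisible(cfg)
}

## gene universe shared across a collection: ids plus mito/coding flags
make_gene_universe <- function(n_genes, mito_frac, coding_frac, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("G%05d", seq_len(n_genes))
    mito <- rep(FALSE, n_genes)
    mito[sample.int(n_genes, round(mito_frac * n_genes))] <- TRUE
    coding <- rep(FALSE, n_genes)
    coding[sample.int(n_genes, round(coding_frac * n_genes))] <- TRUE
    data.frame(gene_id = ids, mito = mito, coding = coding,
               stringsAsFactors = FALSE)
  })
}

#' Generate one synthetic scRNA-seq dataset
#'
#' Draws a negative-binomial cluster mixture as described in
#' [synth_config()].  Mitochondrial genes are up-weighted in a small set of
#' outlier cells so their mitochondrial proportion exceeds typical QC
#' thresholds (> 8% plus several MADs above the median), giving the
#' filtering rules realistic targets.
#'
#' @param config a [synth_config()].
#' @param gene_universe optional data frame (gene_id, mito, coding) shared
#'   across a collection; generated from `config` when `NULL`.
#' @return object of class `synthetic_dataset`: list with `counts` (sparse
#'   genes x cells integer matrix), `true_labels` (named integer vector),
#'   `gene_flags` (data frame), and the `config`.
#' @export
generate_dataset <- function(config, gene_universe = NULL) {
  validate_synth_config(config)
  if (is.null(gene_universe))
    gene_universe <- make_gene_universe(config$n_genes, config$mito_frac,
                                        config$coding_frac, config$seed)
  stopifnot(nrow(gene_universe) == config$n_genes)
  G <- config$n_genes; N <- config$n_cells; K <- config$n_clusters
  withr::with_seed(config$seed, {
    base <- rlnorm(G, meanlog = 0, sdlog = 1.2)
    ## per-cluster profiles: planted log2 fold changes on de_prob of genes
    lfc <- matrix(0, G, K)
    if (K > 1 && config$de_prob > 0) {
      de <- matrix(rbinom(G * K, 1, config$de_prob) == 1, G, K)
      lfc[de] <- rnorm(sum(de), 0, config$logfc_sd)
    }
    prof <- base * 2^lfc               # G x K (recycles base down columns)
    prof <- sweep(prof, 2, colSums(prof), "/")
    labels <- sample(seq_len(K), N, replace = TRUE, prob = config$cluster_props)
    labels[seq_len(K)] <- seq_len(K)   # every true cluster non-empty
    libsize <- rlnorm(N, config$libsize_mu_log, config$libsize_sd_log)
    n_out <- round(config$outlier_cell_frac * N)
    outliers <- if (n_out > 0) sample.int(N, n_out) else integer(0)
    mito <- gene_universe$mito
    counts <- matrix(0L, G, N)
    for (k in seq_len(K)) {
      cells <- which(labels == k)
      if (!length(cells)) next
      p <- prof[, k]
      mu <- outer(p, libsize[cells])
      counts[, cells] <- rnbinom(G * length(cells),
                                 mu = mu, size = config$nb_dispersion)
    }
    ## inflate mitochondrial content of outlier cells: redraw their mito
    ## genes so ~35% of the library is mitochondrial
    if (length(outliers) && any(mito)) {
      for (c in outliers) {
        p <- prof[, labels[c]]
        pm <- p
        pm[mito] <- pm[mito] / sum(pm[mito]) * 0.35
        pm[!mito] <- pm[!mito] / sum(pm[!mito]) * 0.65
        counts[, c] <- rnbinom(G, mu = pm * libsize[c],
                               size = config$nb_dispersion)
      }
    }
    cell_ids <- sprintf("C%05d", seq_len(N))
    dimnames(counts) <- list(gene_universe$gene_id, cell_ids)
    names(labels) <- cell_ids
    structure(list(counts = Matrix::Matrix(counts, sparse = TRUE),
                   true_labels = labels,
                   gene_flags = gene_universe,
                   config = config),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d genes x %d cells, K = %d (seed %d)\n",
              nrow(x$counts), ncol(x$counts), x$config$n_clusters,
              x$config$seed))
  invisible(x)
}

#' Default parameter ranges for a heterogeneous synthetic collection
#'
#' Each entry is a `c(min, max)` pair sampled uniformly per dataset.  The
#' defaults emulate the heterogeneity of a public pan-tissue collection:
#' a few hundred to a couple of thousand cells, 2-8 cell populations,
#' sequencing depths of roughly 2000-8000 counts/cell, and varying
#' dispersion, differential-expression density and outlier-cell load.
#'
#' @return named list of 2-vectors.
#' @export
default_collection_ranges <- function() {
  list(n_cells = c(200, 1500),
       n_clusters = c(2, 8),
       de_prob = c(0.05, 0.3),
       logfc_sd = c(0.5, 1.5),
       libsize_mu_log = c(log(2000), log(8000)),
       libsize_sd_log = c(0.2, 0.5),
       nb_dispersion = c(0.5, 5),
       outlier_cell_frac = c(0, 0.05))
}

#' Generate a collection of heterogeneous synthetic datasets
#'
#' Per-dataset configurations are drawn uniformly within `ranges`; all
#' datasets share one gene universe (ids and mito/coding flags) so that
#' the dataset-by-gene mean-expression matrix needs no gene matching.
#'
#' @param n_datasets number of datasets (>= 2).
#' @param ranges named list of `c(min, max)` ranges, as
#'   [default_collection_ranges()]; integer parameters are rounded.
#' @param n_genes shared gene-universe size.
#' @param mito_frac,coding_frac shared gene-flag fractions.
#' @param seed master seed; per-dataset seeds are split from it.
#' @return named list of `synthetic_dataset` objects ("D01", "D02", ...).
#' @export
generate_dataset_collection <- function(n_datasets,
                                        ranges = default_collection_ranges(),
                                        n_genes = 2000, mito_frac = 0.05,
                                        coding_frac = 0.8, seed = 1L) {
  if (n_datasets < 2) stop_scperf("n_datasets must be >= 2")
  if (!length(ranges)) stop_scperf("ranges must be a non-empty list")
  bad <- vapply(ranges, function(r) length(r) != 2 || any(!is.finite(r)) ||
                  r[2] < r[1], logical(1))
  if (any(bad))
    stop_scperf("each range must be a finite c(min, max) pair")
  universe <- make_gene_universe(n_genes, mito_frac, coding_frac, seed)
  seeds <- split_seed(seed, n_datasets + 1)
  int_par <- c("n_cells", "n_clusters")
  draws <- withr::with_seed(seeds[n_datasets + 1], {
    lapply(seq_len(n_datasets), function(i)
      lapply(ranges, function(r) runif(1, r[1], r[2])))
  })
  out <- lapply(seq_len(n_datasets), function(i) {
    par <- draws[[i]]
    for (p in intersect(int_par, names(par)))
      par[[p]] <- as.integer(round(par[[p]]))
    cfg <- do.call(synth_config,
                   c(par, list(n_genes = n_genes, mito_frac = mito_frac,
                               coding_frac = coding_frac,
                               seed = seeds[i])))
    generate_dataset(cfg, gene_universe = universe)
  })
  names(out) <- sprintf("D%02d", seq_len(n_datasets))
  out
}

#' Planted dataset x pipeline performance model
#'
#' Defines a linear ground-truth surface over dataset and pipeline features
#' with optional interaction structure: planted performance for dataset d
#' and pipeline p is
#' \deqn{y_{dp} = x_d^\top \beta_D + z_p^\top \beta_P +
#'       x_d^\top B z_p + \epsilon,\qquad \epsilon \sim N(0, \sigma^2).}
#' A nonzero interaction matrix `B` makes the best pipeline dataset-specific,
#' which is the signal the meta-models are asked to recover.
#'
#' @param n_dataset_features,n_pipeline_features feature dimensions.
#' @param main_sd,interaction_sd standard deviations of the coefficient
#'   draws; `interaction_sd = 0` plants no dataset specificity.
#' @param interaction_density fraction of interaction cells that are
#'   nonzero.
#' @param noise_sd residual standard deviation (>= 0).
#' @param seed integer seed.
#' @return object of class `planted_performance_model`.
#' @export
planted_performance_model <- function(n_dataset_features, n_pipeline_features,
                                      main_sd = 1, interaction_sd = 1,
                                      interaction_density = 0.25,
                                      noise_sd = 0.5, seed = 1L) {
  if (noise_sd < 0) stop_scperf("noise_sd must be >= 0")
  withr::with_seed(seed, {
    beta_d <- rnorm(n_dataset_features, 0, main_sd)
    beta_p <- rnorm(n_pipeline_features, 0, main_sd)
    B <- matrix(0, n_dataset_features, n_pipeline_features)
    if (interaction_sd > 0 && interaction_density > 0) {
      nz <- rbinom(length(B), 1, interaction_density) == 1
      B[nz] <- rnorm(sum(nz), 0, interaction_sd)
    }
    structure(list(beta_dataset = beta_d, beta_pipeline = beta_p,
                   beta_interaction = B, noise_sd = noise_sd,
                   seed = as.integer(seed)),
              class = "planted_performance_model")
  })
}

#' Generate a performance table from a planted model
#'
#' @param model a [planted_performance_model()].
#' @param dataset_features numeric matrix (datasets x features) with
#'   rownames giving dataset ids.
#' @param pipeline_features numeric matrix (pipelines x features) with
#'   rownames giving pipeline ids.
#' @param metric name of the generated metric column.
#' @return data frame with columns `dataset_id`, `pipeline_id`, and the
#'   planted metric value, one row per dataset-pipeline pair.
#' @export
generate_performance_table <- function(model, dataset_features,
                                       pipeline_features,
                                       metric = "planted") {
  stopifnot(inherits(model, "planted_performance_model"))
  X <- as.matrix(dataset_features); Z <- as.matrix(pipeline_features)
  if (ncol(X) != length(model$beta_dataset) ||
      ncol(Z) != length(model$beta_pipeline))
    stop_scperf("feature layout does not conform to the planted model")
  D <- nrow(X); P <- nrow(Z)
  main_d <- drop(X %*% model$beta_dataset)
  main_p <- drop(Z %*% model$beta_pipeline)
  inter <- X %*% model$beta_interaction %*% t(Z)   # D x P
  vals <- outer(main_d, main_p, "+") + inter
  noise <- withr::with_seed(model$seed + 1L,
    matrix(rnorm(D * P, 0, model$noise_sd), D, P))
  vals <- vals + noise
  ids_d <- rownames(X) %||% sprintf("D%02d", seq_len(D))
  ids_p <- rownames(Z) %||% sprintf("P%03d", seq_len(P))
  out <- data.frame(dataset_id = rep(ids_d, each = P),
                    pipeline_id = rep(ids_p, times = D),
                    stringsAsFactors = FALSE)
  out[[metric]] <- as.vector(t(vals))
  out
}

#' Generate synthetic gene sets over a gene universe
#'
#' Random gene sets for exercising the GSEA metric without external GMT
#' downloads; set sizes are drawn uniformly in `size_range`.
#'
#' @param gene_ids character vector of gene ids.
#' @param n_sets number of sets.
#' @param size_range `c(min, max)` set sizes.
#' @param seed integer seed.
#' @return named list of character vectors (a `GeneSetCollection` shape).
#' @export
generate_gene_sets <- function(gene_ids, n_sets = 25,
                               size_range = c(15, 200), seed = 1L) {
  withr::with_seed(seed, {
    sizes <- sample(seq(size_range[1], size_range[2]), n_sets, replace = TRUE)
    sets <- lapply(sizes, function(s) sample(gene_ids, s))
    names(sets) <- sprintf("SET%03d", seq_len(n_sets))
    sets
  })
}
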