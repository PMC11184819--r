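#' Enumerate the clustering-pipeline grid
#'
#' Builds the Cartesian product of pipeline choices in deterministic order
#' (filtering varies slowest, resolution fastest) with stable pipeline ids.
#' The default levels — 3 filtering strategies x 3 normalizations x
#' 4 PCA dimensionalities x 8 clustering resolutions — give the standard
#' 288-pipeline grid.
#'
#' @param filtering,normalization,n_dims,resolution level vectors for the
#'   four pipeline steps.
#' @return data frame of class `pipeline_grid` with a `pipeline_id` column
#'   and one row per configuration.
#' @export
enumerate_grid <- function(filtering = c("default", "stringent", "lenient"),
                           normalization = c("lognorm", "pooling", "pearson"),
                           n_dims = c(10, 15, 20, 30),
                           resolution = c(0.1, 0.2, 0.3, 0.5, 0.8, 1.0, 1.2, 2.0)) {
  levels <- list(filtering = filtering, normalization = normalization,
                 n_dims = n_dims, resolution = resolution)
  if (any(!lengths(levels)))
    stop_scperf("every pipeline step needs at least one level")
  grid <- expand.grid(resolution = resolution, n_dims = n_dims,
                      normalization = normalization, filtering = filtering,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("filtering", "normalization", "n_dims", "resolution")]
  grid$pipeline_id <- sprintf("P%03d", seq_len(nrow(grid)))
  rownames(grid) <- NULL
  class(grid) <- c("pipeline_grid", "data.frame")
  grid
}

get_counts <- function(x) {
  if (inherits(x, "synthetic_dataset")) x$counts else x
}
get_gene_flags <- function(x) {
  if (inherits(x, "synthetic_dataset")) x$gene_flags else
    attr(x, "gene_flags")
}

#' Per-cell quality-control metrics
#'
#' Standard per-cell QC (library size, detected features, percentage of
#' counts in the top-N expressed features, mitochondrial proportion) is
#' computed with `scuttle::perCellQCMetrics`; `featcount_dist` — the
#' residual of per-cell log10 detected features from a tricube-weighted
#' degree-2 local regression on log10 total counts — is computed here.
#' Cells with zero total counts are flagged (`zero_total`) and their QC
#' fields set to `NA`.
#'
#' @param counts genes x cells count matrix (dense or sparse), or a
#'   `synthetic_dataset`.
#' @param gene_flags optional data frame with logical `mito` (and `coding`)
#'   columns; taken from the dataset object when available.
#' @return data frame of class `cell_qc` with one row per cell.  The
#'   `pct_counts_in_top_*` columns are on the 0-100 scale; `pct_counts_Mt`
#'   is a proportion in `[0, 1]`.
#' @export
compute_cell_qc <- function(counts, gene_flags = NULL) {
  gene_flags <- gene_flags %||% get_gene_flags(counts)
  m <- get_counts(counts)
  if (!nrow(m) || !ncol(m)) stop_scperf("counts must be non-empty")
  mito <- if (!is.null(gene_flags)) which(gene_flags$mito) else integer(0)
  subsets <- if (length(mito)) list(Mt = mito) else NULL
  pc <- scuttle::perCellQCMetrics(m, subsets = subsets,
                                  percent.top = c(20, 50, 100, 200))
  total <- pc$sum
  detected <- pc$detected
  qc <- data.frame(
    cell_id = colnames(m) %||% sprintf("C%05d", seq_len(ncol(m))),
    total_counts = total,
    detected_features = detected,
    log10_total_counts = log10(total),
    log10_total_features = log10(detected),
    pct_counts_in_top_20_features = pc$percent.top_20,
    pct_counts_in_top_50_features = pc$percent.top_50,
    pct_counts_in_top_100_features = pc$percent.top_100,
    pct_counts_in_top_200_features = pc$percent.top_200,
    pct_counts_Mt = if (length(mito)) pc$subsets_Mt_percent / 100 else 0,
    stringsAsFactors = FALSE)
  qc$zero_total <- total == 0
  qc$featcount_dist <- NA_real_
  ok <- !qc$zero_total
  qc$featcount_dist[ok] <- local_fit_residuals(qc$log10_total_counts[ok],
                                               qc$log10_total_features[ok])
  qc[qc$zero_total, setdiff(names(qc), c("cell_id", "zero_total",
                                         "total_counts",
                                         "detected_features"))] <- NA
  class(qc) <- c("cell_qc", "data.frame")
  qc
}

## two-sided / directional MAD outlier flags for one metric
mad_flag <- function(x, lower_nmads = NULL, upper_nmads = NULL) {
  med <- median(x, na.rm = TRUE)
  dev <- mad(x, na.rm = TRUE)            # 1.4826 consistency constant
  flag <- rep(FALSE, length(x))
  if (!is.null(lower_nmads)) flag <- flag | (x < med - lower_nmads * dev)
  if (!is.null(upper_nmads)) flag <- flag | (x > med + upper_nmads * dev)
  flag[is.na(x)] <- FALSE
  flag
}

#' Filter cells with MAD-based outlier rules
#'
#' Three strategies over five QC metrics (log10 total counts, log10
#' detected features, % counts in top-20 features, featcount_dist,
#' mitochondrial proportion):
#' \itemize{
#'  \item `default`: flags are log10 counts/features below median - 5 MADs
#'    or above median + 2.5 MADs; top-20 percentage and featcount_dist
#'    beyond 5 MADs either side; mitochondrial proportion above
#'    median + 2.5 MADs *and* above 0.08.  A cell is removed when it
#'    carries at least two flags.
#'  \item `stringent`: same flags, removal on at least one flag.
#'  \item `lenient`: two-sided 5-MAD flags on the four non-mitochondrial
#'    metrics; mitochondrial flag when above median + 3 MADs *or* above
#'    0.08; removal on at least two flags.
#' }
#' Zero-total cells are always removed.
#'
#' @param qc a [compute_cell_qc()] table.
#' @param strategy `"default"`, `"stringent"` or `"lenient"`.
#' @return character vector of kept cell ids.
#' @export
filter_cells <- function(qc, strategy = c("default", "stringent", "lenient")) {
  strategy <- match.arg(strategy)
  flags <- switch(strategy,
    default = ,
    stringent = cbind(
      mad_flag(qc$log10_total_counts, lower_nmads = 5, upper_nmads = 2.5),
      mad_flag(qc$log10_total_features, lower_nmads = 5, upper_nmads = 2.5),
      mad_flag(qc$pct_counts_in_top_20_features, 5, 5),
      mad_flag(qc$featcount_dist, 5, 5),
      mad_flag(qc$pct_counts_Mt, upper_nmads = 2.5) & qc$pct_counts_Mt > 0.08),
    lenient = cbind(
      mad_flag(qc$log10_total_counts, 5, 5),
      mad_flag(qc$log10_total_features, 5, 5),
      mad_flag(qc$pct_counts_in_top_20_features, 5, 5),
      mad_flag(qc$featcount_dist, 5, 5),
      mad_flag(qc$pct_counts_Mt, upper_nmads = 3) | qc$pct_counts_Mt > 0.08))
  flags[is.na(flags)] <- FALSE
  n_flags <- rowSums(flags)
  min_flags <- if (strategy == "stringent") 1 else 2
  keep <- n_flags < min_flags & !qc$zero_total
  qc$cell_id[keep]
}

#' Normalize a count matrix
#'
#' Three normalization strategies mirroring the popular single-cell
#' toolchain:
#' \itemize{
#'  \item `lognorm`: \eqn{\log(1 + 10^4 x_{gc}/\ell_c)} with \eqn{\ell_c}
#'    the cell library size.
#'  \item `pooling`: pooling-deconvolution size factors — cells are ordered
#'    by library size, overlapping ring pools of 20 cells give pooled
#'    factors (median ratio of pooled counts to the average normalized
#'    cell profile), and per-cell factors solve the resulting linear
#'    system by least squares; counts are scaled by the (mean-1) factors
#'    and log1p-transformed.
#'  \item `pearson`: analytic Pearson residuals under an NB null with
#'    \eqn{\theta = 100} and a rank-1 mean \eqn{\mu_{gc}} from row/column
#'    totals, clipped to \eqn{\pm\sqrt{n_{cells}}}.
#' }
#'
#' @param counts genes x cells matrix of raw counts (cells already
#'   filtered); cells with zero totals are an error.
#' @param method one of `"lognorm"`, `"pooling"`, `"pearson"`.
#' @param pool_size ring-pool size for `pooling`.
#' @param theta NB dispersion for `pearson`.
#' @return normalized genes x cells matrix (sparse for `lognorm`/`pooling`,
#'   dense for `pearson`).
#' @export
normalize_counts <- function(counts, method = c("lognorm", "pooling", "pearson"),
                             pool_size = 20, theta = 100) {
  method <- match.arg(method)
  m <- get_counts(counts)
  libsize <- Matrix::colSums(m)
  if (any(libsize == 0))
    stop_scperf("zero-library cells present; filter them before normalizing")
  scale_cols <- function(m, sf) {
    out <- m %*% Matrix::Diagonal(x = 1 / sf)
    dimnames(out) <- dimnames(m)
    out
  }
  switch(method,
    lognorm = log1p(scale_cols(m, libsize / 1e4)),
    pooling = log1p(scale_cols(m, pooling_size_factors(m, pool_size = pool_size))),
    pearson = {
      x <- as.matrix(m)
      n <- ncol(x)
      mu <- outer(Matrix::rowSums(x), libsize) / sum(libsize)
      r <- (x - mu) / sqrt(mu + mu^2 / theta)
      r[!is.finite(r)] <- 0
      clip <- sqrt(n)
      pmin(pmax(r, -clip), clip)
    })
}

#' Pooling-deconvolution size factors
#'
#' Simplified pooling deconvolution: cells ordered by library size form
#' overlapping ring pools; each pool's summed profile is compared with the
#' average normalized cell profile by a median ratio, and the per-cell
#' factors solving the pooled linear system in the least-squares sense are
#' rescaled to mean 1.
#'
#' @param m genes x cells count matrix.
#' @param pool_size cells per pool (capped at the number of cells).
#' @return positive numeric vector of size factors, mean 1.
#' @export
pooling_size_factors <- function(m, pool_size = 20) {
  n <- ncol(m)
  libsize <- Matrix::colSums(m)
  if (n < 4) return(libsize / mean(libsize))
  ## two coprime ring sizes keep the pooled design full rank (a single
  ## consecutive-ones circulant is singular whenever the ring size shares
  ## a factor with n)
  ps1 <- min(pool_size, n - 1)
  sizes <- unique(c(ps1, min(ps1 + 1, n - 1)))
  ord <- order(libsize)
  ref <- Matrix::rowMeans(m %*% Matrix::Diagonal(x = 1 / libsize))
  use <- ref > 0
  A <- matrix(0, n * length(sizes), n)
  t_pool <- numeric(nrow(A))
  row <- 0
  for (ps in sizes) {
    for (i in seq_len(n)) {
      row <- row + 1
      pool <- ord[((i - 1 + seq_len(ps) - 1) %% n) + 1]
      A[row, pool] <- 1
      y <- Matrix::rowSums(m[, pool, drop = FALSE])
      t_pool[row] <- median(y[use] / ref[use])
    }
  }
  s <- qr.coef(qr(A), t_pool)
  bad <- !is.finite(s) | s <= 0
  if (all(bad)) return(libsize / mean(libsize))
  s[bad] <- min(s[!bad])
  s / mean(s)
}

#' Rank genes by vst-style standardized variance
#'
#' Fits a local regression of log10 gene variance on log10 gene mean,
#' standardizes each gene by its predicted standard deviation (values
#' clipped at \eqn{\sqrt{n_{cells}}}), and ranks genes by the variance of
#' the standardized values.  Ties break by original gene order.
#'
#' @param m genes x cells matrix (raw or normalized counts).
#' @param n number of genes to return (default 2000).
#' @param span loess span for the mean-variance trend.
#' @return character vector of the top `n` gene ids.
#' @export
select_hvgs <- function(m, n = 2000, span = 0.3) {
  m <- get_counts(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("G%05d", seq_len(nrow(m)))
  nc <- ncol(m)
  mu <- Matrix::rowMeans(m)
  v <- Matrix::rowSums((m - mu)^2) / (nc - 1)
  pos <- v > 0 & mu > 0
  if (!any(pos)) {
    warning("no genes with nonzero variance")
    return(character(0))
  }
  fit_res <- rep(NA_real_, nrow(m))
  lx <- log10(mu[pos]); ly <- log10(v[pos])
  pred <- ly - local_fit_residuals(lx, ly, span = span, degree = 2)
  sd_pred <- sqrt(10^pred)
  ## variance of clipped standardized counts
  clip <- sqrt(nc)
  mp <- as.matrix(m[pos, , drop = FALSE])
  z <- (mp - mu[pos]) / sd_pred
  z <- pmin(pmax(z, -clip), clip)
  std_var <- rowSums((z - rowMeans(z))^2) / (nc - 1)
  ranked <- rownames(m)[pos][order(-std_var, seq_along(std_var))]
  if (length(ranked) < n) {
    warning(sprintf("only %d genes with nonzero variance (< n = %d)",
                    length(ranked), n))
    return(ranked)
  }
  head(ranked, n)
}

#' PCA cell embeddings
#'
#' Genes are centered and unit-scaled (zero-variance genes dropped), then
#' the top principal component scores are computed by SVD.  Sign
#' convention: the largest-magnitude gene loading of each component is
#' positive.
#'
#' @param m genes x cells normalized matrix restricted to HVGs.
#' @param n_dims number of components; must be `< min(n_cells, n_genes)`.
#' @return cells x `n_dims` score matrix with cell rownames.
#' @export
reduce_dims <- function(m, n_dims) {
  m <- as.matrix(get_counts(m))
  if (n_dims >= min(dim(m)))
    stop_scperf("n_dims must be smaller than both the number of cells and genes")
  sds <- apply(m, 1, sd)
  keep <- sds > 0
  x <- t((m[keep, , drop = FALSE] - rowMeans(m[keep, , drop = FALSE])) /
           sds[keep])                       # cells x genes, scaled
  if (n_dims >= min(dim(x)))
    stop_scperf("n_dims too large after dropping constant genes")
  sv <- svd(x, nu = n_dims, nv = n_dims)
  flip <- vapply(seq_len(n_dims), function(j) {
    l <- sv$v[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sv$u %*% diag(sv$d[seq_len(n_dims)], n_dims) %*% diag(flip, n_dims)
  rownames(scores) <- colnames(m)
  colnames(scores) <- sprintf("PC%d", seq_len(n_dims))
  scores
}

#' Shared-nearest-neighbor Louvain clustering
#'
#' Builds a k = 20 nearest-neighbor graph on the embeddings, re-weights
#' edges by the Jaccard overlap of neighbor sets, prunes edges with
#' overlap below 1/15, and optimizes modularity with Louvain at the given
#' resolution.  Deterministic given `seed`.
#'
#' @param emb cells x dims embedding matrix with cell rownames.
#' @param resolution Louvain resolution parameter.
#' @param k number of neighbors (reduced with a warning when cells <= k).
#' @param prune Jaccard pruning threshold.
#' @param seed integer seed for the Louvain heuristic.
#' @return named integer vector of cluster labels (1-based).
#' @export
cluster_graph <- function(emb, resolution, k = 20, prune = 1 / 15, seed = 42L) {
  n <- nrow(emb)
  if (n < 2) stop_scperf("need at least 2 cells to cluster")
  if (n <= k) {
    warning(sprintf("only %d cells; reducing k to %d", n, n - 1))
    k <- n - 1
  }
  d <- as.matrix(dist(emb))
  nn <- t(apply(d, 1, function(r) order(r)[2:(k + 1)]))
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                              j = as.vector(t(nn)), x = 1,
                              dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x)
  jac[jac < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  cl <- withr::with_seed(seed,
    igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                            resolution = resolution))
  labels <- as.integer(igraph::membership(cl))
  names(labels) <- rownames(emb)
  labels
}

#' Run one clustering pipeline on a dataset
#'
#' Composes QC -> filtering -> normalization -> HVG selection (2000) ->
#' PCA -> SNN-Louvain clustering according to a single grid configuration.
#'
#' @param dataset a `synthetic_dataset` (or genes x cells count matrix with
#'   a `gene_flags` attribute).
#' @param config one row of a [enumerate_grid()] grid (or a list with
#'   `filtering`, `normalization`, `n_dims`, `resolution`, `pipeline_id`).
#' @param seed integer seed for the clustering heuristic.
#' @param dataset_id identifier recorded in the result.
#' @param n_hvgs number of highly variable genes used for PCA.
#' @return object of class `clustering_result`: `kept_cell_ids`, `labels`,
#'   `k`, `singular` flag (k == 1), `pipeline_id`, `dataset_id`, and
#'   `error` (`NULL` on success; on failure only the error message and ids
#'   are populated).
#' @export
run_pipeline <- function(dataset, config, seed = 42L, dataset_id = "D01",
                         n_hvgs = 2000) {
  config <- as.list(config)
  res <- tryCatch({
    qc <- compute_cell_qc(dataset)
    kept <- filter_cells(qc, config$filtering)
    if (length(kept) < 2) stop_scperf("all cells filtered out")
    m <- get_counts(dataset)[, kept, drop = FALSE]
    norm <- normalize_counts(m, config$normalization)
    hvgs <- suppressWarnings(select_hvgs(if (config$normalization == "pearson")
      m else norm, n = n_hvgs))
    nd <- min(config$n_dims, length(hvgs) - 1, length(kept) - 1)
    emb <- reduce_dims(norm[hvgs, , drop = FALSE], nd)
    labels <- cluster_graph(emb, config$resolution, seed = seed)
    k <- length(unique(labels))
    structure(list(dataset_id = dataset_id,
                   pipeline_id = config$pipeline_id %||% NA_character_,
                   kept_cell_ids = kept, labels = labels, k = k,
                   singular = k == 1, error = NULL),
              class = "clustering_result")
  }, error = function(e) {
    structure(list(dataset_id = dataset_id,
                   pipeline_id = config$pipeline_id %||% NA_character_,
                   kept_cell_ids = character(0), labels = NULL,
                   k = NA_integer_, singular = NA, error = conditionMessage(e)),
              class = "clustering_result")
  })
  res
}

#' Run the pipeline grid over a dataset collection
#'
#' Executes every dataset x configuration combination; per-run failures are
#' captured as error records and never abort the sweep.  Results are cached
#' (keyed on dataset and pipeline id) in an environment so a rerun with the
#' same cache is idempotent.
#'
#' @param datasets named list of datasets.
#' @param grid a [enumerate_grid()] data frame.
#' @param seed integer seed shared by every clustering run.
#' @param cache optional environment used as a result cache.
#' @param verbose print progress.
#' @return list of `clustering_result` objects, named
#'   `"<dataset_id>.<pipeline_id>"`.
#' @export
run_grid <- function(datasets, grid, seed = 42L, cache = NULL,
                     verbose = FALSE) {
  if (!length(datasets) || !nrow(grid)) stop_scperf("empty datasets or grid")
  if (is.null(names(datasets)))
    names(datasets) <- sprintf("D%02d", seq_along(datasets))
  out <- vector("list", length(datasets) * nrow(grid))
  keys <- character(length(out))
  idx <- 0
  for (d in names(datasets)) {
    for (i in seq_len(nrow(grid))) {
      idx <- idx + 1
      key <- paste(d, grid$pipeline_id[i], sep = ".")
      keys[idx] <- key
      if (!is.null(cache) && !is.null(cache[[key]])) {
        out[[idx]] <- cache[[key]]
        next
      }
      r <- run_pipeline(datasets[[d]], grid[i, ], seed = seed, dataset_id = d)
      if (!is.null(cache)) cache[[key]] <- r
      out[[idx]] <- r
      if (verbose) message(key, ": k = ", r$k)
    }
  }
  names(out) <- keys
  out
}
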