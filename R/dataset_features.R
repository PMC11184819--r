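#' Names of the 21 dataset-level QC summary statistics
#' @return character vector of length 21.
#' @export
dataset_qc_feature_names <- function() {
  c("median_log10_total_counts", "median_log10_detected_features",
    "median_pct_top_20", "median_pct_top_50", "median_pct_top_100",
    "median_pct_top_200", "median_pct_mito", "median_featcount_dist",
    "median_coding_prop", "log10_n_cells", "log10_genes_detected",
    "median_prop_genes_detected", "mad_log10_total_counts",
    "mad_log10_detected_features", "frac_cells_high_mito", "sparsity",
    "cv_libsize", "iqr_pct_top_50", "skew_log10_libsize",
    "median_counts_per_gene", "frac_genes_coding")
}

#' Summarize a dataset into 21 QC statistics
#'
#' Medians of the per-cell QC metrics plus dataset-level shape statistics
#' (cell/gene counts, sparsity, library-size dispersion and skewness,
#' high-mitochondrial-cell fraction, coding-genome fractions).  These are
#' the dataset characteristics handed to the meta-models.
#'
#' @param qc a [compute_cell_qc()] table.
#' @param counts the genes x cells count matrix the QC was computed from.
#' @param gene_flags data frame with `mito`/`coding` flags; coding-based
#'   fields are `NA` when absent.
#' @return named numeric vector of length 21.
#' @export
summarize_dataset_qc <- function(qc, counts, gene_flags = NULL) {
  gene_flags <- gene_flags %||% get_gene_flags(counts)
  m <- get_counts(counts)
  if (nrow(qc) < 2) stop_scperf("need at least 2 cells")
  ok <- !qc$zero_total
  libsize <- qc$total_counts[ok]
  coding_prop <- if (!is.null(gene_flags) && any(gene_flags$coding)) {
    Matrix::colSums(m[gene_flags$coding, ok, drop = FALSE]) / libsize
  } else NA_real_
  out <- c(
    median_log10_total_counts = median(qc$log10_total_counts[ok]),
    median_log10_detected_features = median(qc$log10_total_features[ok]),
    median_pct_top_20 = median(qc$pct_counts_in_top_20_features[ok]),
    median_pct_top_50 = median(qc$pct_counts_in_top_50_features[ok]),
    median_pct_top_100 = median(qc$pct_counts_in_top_100_features[ok]),
    median_pct_top_200 = median(qc$pct_counts_in_top_200_features[ok]),
    median_pct_mito = median(qc$pct_counts_Mt[ok]),
    median_featcount_dist = median(qc$featcount_dist[ok]),
    median_coding_prop = median(coding_prop),
    log10_n_cells = log10(nrow(qc)),
    log10_genes_detected = log10(sum(Matrix::rowSums(m) > 0)),
    median_prop_genes_detected = median(qc$detected_features[ok]) / nrow(m),
    mad_log10_total_counts = mad(qc$log10_total_counts[ok]),
    mad_log10_detected_features = mad(qc$log10_total_features[ok]),
    frac_cells_high_mito = mean(qc$pct_counts_Mt[ok] > 0.08),
    sparsity = 1 - Matrix::nnzero(m) / prod(dim(m)),
    cv_libsize = sd(libsize) / mean(libsize),
    iqr_pct_top_50 = IQR(qc$pct_counts_in_top_50_features[ok]),
    skew_log10_libsize = moment_skewness(qc$log10_total_counts[ok]),
    median_counts_per_gene = median(Matrix::rowSums(m)),
    frac_genes_coding = if (!is.null(gene_flags)) mean(gene_flags$coding)
      else NA_real_)
  stopifnot(identical(names(out), dataset_qc_feature_names()))
  out
}

#' Dataset-by-gene mean-expression matrix
#'
#' One row per dataset holding the mean raw count of every gene over the
#' dataset's cells; differing gene universes are intersected with a
#' warning.
#'
#' @param collection named list of datasets.
#' @return datasets x genes numeric matrix.
#' @export
mean_expression_matrix <- function(collection) {
  genes <- lapply(collection, function(d) rownames(get_counts(d)))
  shared <- Reduce(intersect, genes)
  if (any(vapply(genes, length, integer(1)) != length(shared)))
    warning("gene universes differ; intersecting")
  rows <- t(vapply(collection, function(d)
    Matrix::rowMeans(get_counts(d)[shared, , drop = FALSE]),
    numeric(length(shared))))
  rownames(rows) <- names(collection)
  colnames(rows) <- shared
  rows
}

#' Fit probabilistic PCA (closed-form maximum likelihood)
#'
#' Tipping-Bishop ML solution on the column-centered data: with sample
#' covariance eigenpairs \eqn{(\lambda_j, u_j)},
#' \eqn{\sigma^2 = \mathrm{mean}_{j>q}\lambda_j} and
#' \eqn{W = U_q(\Lambda_q - \sigma^2 I)^{1/2}}.  Computed via the SVD of
#' the centered matrix, so it stays cheap when rows (datasets) are far
#' fewer than columns (genes).
#'
#' @param X rows x columns data matrix (datasets x genes).
#' @param q number of components (default 20); requires `nrow(X) >= q + 1`.
#' @return object of class `ppca_model` with `mu`, `W`, `sigma2`, `q`.
#' @export
fit_ppca <- function(X, q = 20) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < q + 1) stop_scperf("need at least q + 1 = ", q + 1, " rows")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = q)
  lambda <- rep(0, p)
  lambda[seq_along(sv$d)] <- sv$d^2 / n          # ML covariance eigenvalues
  if (q >= sum(sv$d > 1e-12)) {
    warning("q >= rank of the centered data; sigma2 set to 0")
    sigma2 <- 0
  } else {
    sigma2 <- mean(lambda[(q + 1):p])
  }
  gain <- sqrt(pmax(lambda[seq_len(q)] - sigma2, 0))
  W <- sv$v %*% diag(gain, q)
  rownames(W) <- colnames(X)
  structure(list(mu = mu, W = W, sigma2 = sigma2, q = q),
            class = "ppca_model")
}

#' Posterior-mean PPCA scores
#'
#' Projects rows of `X` with a fitted model:
#' \eqn{z = (W^\top W + \sigma^2 I)^{-1} W^\top (x - \mu)}.  Train and test
#' rows must be transformed with the same (train-fitted) model.
#'
#' @param model a [fit_ppca()] model.
#' @param X rows x genes matrix over the model's gene universe.
#' @return rows x q score matrix (columns `PC1..PCq`).
#' @export
transform_ppca <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$mu))
    stop_scperf("gene universe does not match the fitted model")
  M <- crossprod(model$W) + model$sigma2 * diag(model$q)
  Z <- t(solve(M, t(sweep(X, 2, model$mu) %*% model$W)))
  colnames(Z) <- sprintf("PC%d", seq_len(model$q))
  rownames(Z) <- rownames(X)
  Z
}

#' Standardize feature columns with train-set statistics
#'
#' Column means and standard deviations are computed on the train rows
#' only and applied to every row, preventing train-test leakage.
#' Zero-variance train columns are set to 0 with a warning.
#'
#' @param table data frame with a `dataset_id` column and numeric features.
#' @param train_ids dataset ids forming the train set.
#' @return list with `table` (scaled), `center`, `scale`.
#' @export
scale_features <- function(table, train_ids) {
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  tr <- table$dataset_id %in% train_ids
  if (!any(tr)) stop_scperf("no train rows found")
  center <- vapply(table[tr, num, drop = FALSE], mean, numeric(1), na.rm = TRUE)
  scale <- vapply(table[tr, num, drop = FALSE], sd, numeric(1), na.rm = TRUE)
  for (j in num) {
    if (!is.finite(scale[j]) || scale[j] == 0) {
      warning("zero train variance in feature ", j, "; set to 0")
      table[[j]] <- 0
      scale[j] <- 1
    } else {
      table[[j]] <- (table[[j]] - center[j]) / scale[j]
    }
  }
  list(table = table, center = center, scale = scale)
}

#' Build the dataset feature table (21 QC + 20 PPCA features)
#'
#' Computes the 21 QC summary statistics per dataset, fits PPCA with
#' `q = 20` on the train rows of the dataset-by-gene mean-expression
#' matrix, transforms all rows with the train-fitted model, and
#' standardizes every feature with train-set statistics.
#'
#' @param collection named list of datasets.
#' @param train_ids dataset ids used to fit the PPCA model and the scaling.
#' @param q number of PPCA components.
#' @return list with `table` (dataset_id + 41 scaled features), `ppca`
#'   (the train-fitted model), `center`, `scale`.
#' @export
build_dataset_features <- function(collection, train_ids, q = 20) {
  qc_rows <- t(vapply(collection, function(d) {
    qc <- compute_cell_qc(d)
    summarize_dataset_qc(qc, d)
  }, numeric(21)))
  me <- mean_expression_matrix(collection)
  train_ids <- intersect(train_ids, rownames(me))
  model <- fit_ppca(me[train_ids, , drop = FALSE], q = q)
  scores <- transform_ppca(model, me)
  table <- data.frame(dataset_id = names(collection), qc_rows, scores,
                      stringsAsFactors = FALSE, check.names = FALSE)
  rownames(table) <- NULL
  scaled <- scale_features(table, train_ids)
  list(table = scaled$table, ppca = model,
       center = scaled$center, scale = scaled$scale)
}
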