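#' Expression input for cluster-purity metrics
#'
#' Restricts the raw count matrix to the cells kept by a clustering run and
#' to the 500 most highly variable genes (ranked on this restricted
#' matrix), then applies a log(x + 1) transform.
#'
#' @param counts genes x cells raw counts (or `synthetic_dataset`).
#' @param clustering a `clustering_result`.
#' @param n_genes number of HVGs (all available, with a warning, when
#'   fewer have nonzero variance).
#' @return dense cells x genes matrix ready for [calinski_harabasz()],
#'   [davies_bouldin_neg()], [silhouette_mean()].
#' @export
purity_input <- function(counts, clustering, n_genes = 500) {
  m <- get_counts(counts)
  stopifnot(all(clustering$kept_cell_ids %in% colnames(m)))
  m <- m[, clustering$kept_cell_ids, drop = FALSE]
  hvgs <- suppressWarnings(select_hvgs(m, n = n_genes))
  t(as.matrix(log1p(m[hvgs, , drop = FALSE])))
}

check_labels <- function(X, labels) {
  stopifnot(nrow(X) == length(labels))
  as.integer(factor(labels))
}

#' Calinski-Harabasz index
#'
#' Ratio of between- to within-cluster dispersion scaled by degrees of
#' freedom: \eqn{CH = [B/(k-1)] / [W/(n-k)]} with
#' \eqn{B = \sum_c n_c \|\mu_c - \mu\|^2},
#' \eqn{W = \sum_c \sum_{i \in c} \|x_i - \mu_c\|^2}.  Higher is better.
#'
#' @param X points x features matrix.
#' @param labels cluster assignment per row of `X`.
#' @return CH value; `NA` when k = 1; `Inf` when W = 0; error when k = n.
#' @export
calinski_harabasz <- function(X, labels) {
  X <- as.matrix(X)
  lab <- check_labels(X, labels)
  k <- max(lab); n <- nrow(X)
  if (k == 1) return(NA_real_)
  if (k == n) stop_scperf("k = n leaves zero within-cluster degrees of freedom")
  mu <- colMeans(X)
  B <- 0; W <- 0
  for (c in seq_len(k)) {
    Xc <- X[lab == c, , drop = FALSE]
    muc <- colMeans(Xc)
    B <- B + nrow(Xc) * sum((muc - mu)^2)
    W <- W + sum(sweep(Xc, 2, muc)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Negated Davies-Bouldin index
#'
#' \eqn{DB = k^{-1} \sum_i \max_{j \ne i} (s_i + s_j)/d_{ij}} with
#' \eqn{s_i} the mean Euclidean distance of cluster-i points to their
#' centroid and \eqn{d_{ij}} the centroid distance.  Lower DB is better,
#' so the value is returned negated to share the "higher is better"
#' orientation of the other metrics.
#'
#' @inheritParams calinski_harabasz
#' @return `-DB`; `NA` when k = 1 or when two centroids coincide.
#' @export
davies_bouldin_neg <- function(X, labels) {
  X <- as.matrix(X)
  lab <- check_labels(X, labels)
  k <- max(lab)
  if (k == 1) return(NA_real_)
  cent <- t(vapply(seq_len(k), function(c) colMeans(X[lab == c, , drop = FALSE]),
                   numeric(ncol(X))))
  s <- vapply(seq_len(k), function(c) {
    Xc <- X[lab == c, , drop = FALSE]
    mean(sqrt(rowSums(sweep(Xc, 2, cent[c, ])^2)))
  }, numeric(1))
  dmat <- as.matrix(dist(cent))
  if (any(dmat[upper.tri(dmat)] == 0)) return(NA_real_)
  r <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i),
               function(j) (s[i] + s[j]) / dmat[i, j], numeric(1)))
  }, numeric(1))
  -mean(r)
}

#' Mean silhouette coefficient
#'
#' Mean over points of \eqn{(b - a)/\max(a, b)} where `a` is the mean
#' intra-cluster distance (excluding self) and `b` the smallest mean
#' distance to another cluster.  The silhouette of a singleton cluster
#' point is 0.  Bounded in `[-1, 1]`.
#'
#' @inheritParams calinski_harabasz
#' @return mean silhouette; `NA` when k = 1.
#' @export
silhouette_mean <- function(X, labels) {
  X <- as.matrix(X)
  lab <- check_labels(X, labels)
  k <- max(lab); n <- nrow(X)
  if (k == 1) return(NA_real_)
  d <- as.matrix(dist(X))
  sizes <- tabulate(lab, k)
  ## mean distance from each point to each cluster
  md <- vapply(seq_len(k), function(c) rowSums(d[, lab == c, drop = FALSE]),
               numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- lab[i]
    if (sizes[ci] == 1) { s[i] <- 0; next }
    a <- md[i, ci] / (sizes[ci] - 1)
    b <- min(md[i, -ci] / sizes[-ci])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the contingency table under the permutation model.
#'
#' @param labels_a,labels_b cluster assignments over the same items (same
#'   length and, when named, the same names).
#' @return ARI in `[-1, 1]`; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop_scperf("labelings must cover the same cells")
  if (!is.null(names(labels_a)) && !is.null(names(labels_b)))
    labels_b <- labels_b[names(labels_a)]
  n <- length(labels_a)
  if (n < 2) stop_scperf("need at least 2 shared cells")
  tab <- table(labels_a, labels_b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  exp_idx <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(0)   # both partitions trivial
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}
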