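#' One-vs-rest marker ranking per cluster
#'
#' For every cluster, ranks all genes by the log2 fold change of mean
#' expression (pseudocount 1) in the cluster versus all other cells.
#' Ties break by gene id so the ranking is strict.
#'
#' @param normalized genes x cells expression matrix.
#' @param labels cluster assignment per cell (column).
#' @return named list (one entry per cluster) of named numeric vectors of
#'   log2 fold changes, sorted decreasing; clusters of a single cell carry
#'   a `low_confidence` attribute.
#' @export
find_markers <- function(normalized, labels) {
  m <- get_counts(normalized)
  lab <- as.integer(factor(labels))
  k <- max(lab)
  if (k < 2) stop_scperf("marker ranking needs at least 2 clusters")
  gene_ids <- rownames(m) %||% sprintf("G%05d", seq_len(nrow(m)))
  out <- lapply(seq_len(k), function(c) {
    in_c <- lab == c
    lfc <- log2(Matrix::rowMeans(m[, in_c, drop = FALSE]) + 1) -
      log2(Matrix::rowMeans(m[, !in_c, drop = FALSE]) + 1)
    names(lfc) <- gene_ids
    lfc <- lfc[order(-lfc, gene_ids)]
    if (sum(in_c) == 1) attr(lfc, "low_confidence") <- TRUE
    lfc
  })
  names(out) <- levels(factor(labels))
  out
}

#' GSEA enrichment score (weighted Kolmogorov-Smirnov statistic)
#'
#' Walks the ranked gene list accumulating \eqn{|s_i|^p / \sum_{hits}|s|^p}
#' on set members and \eqn{-1/(N - N_{hits})} otherwise; the ES is the
#' signed maximum deviation of the running sum.
#'
#' @param stats named numeric vector of ranking statistics, sorted
#'   decreasing.
#' @param set character vector of gene ids.
#' @param p weight exponent (1 = classic weighted; 0 = unweighted KS).
#' @return ES in `[-1, 1]`; `NA` when the set has no overlap with the
#'   ranking; error when the set covers the whole list.
#' @export
gsea_es <- function(stats, set, p = 1) {
  hits <- names(stats) %in% set
  nh <- sum(hits)
  if (nh == 0) return(NA_real_)
  N <- length(stats)
  if (nh == N) stop_scperf("gene set equals the whole ranked list")
  w <- abs(stats)^p
  inc <- numeric(N)
  denom <- sum(w[hits])
  inc[hits] <- if (denom > 0) w[hits] / denom else 1 / nh
  inc[!hits] <- -1 / (N - nh)
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Normalized enrichment score by gene-label permutation
#'
#' NES = ES / mean(|ES*|) over permutation enrichment scores with the same
#' sign as the observed ES, where permutations shuffle which genes belong
#' to the set (set positions are redrawn uniformly).
#'
#' @inheritParams gsea_es
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return NES; `NA` when the observed ES is `NA` or no permutation ES
#'   shares its sign.
#' @export
gsea_nes <- function(stats, set, n_perm = 1000, p = 1, seed = 1L) {
  if (n_perm < 100) stop_scperf("n_perm must be >= 100")
  es <- gsea_es(stats, set, p = p)
  if (is.na(es)) return(NA_real_)
  nh <- sum(names(stats) %in% set)
  N <- length(stats)
  w <- abs(stats)^p
  miss_dec <- -1 / (N - nh)
  perm_es <- withr::with_seed(seed, vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(N, nh)
    inc <- rep(miss_dec, N)
    denom <- sum(w[idx])
    inc[idx] <- if (denom > 0) w[idx] / denom else 1 / nh
    run <- cumsum(inc)
    run[which.max(abs(run))]
  }, numeric(1)))
  same <- perm_es[sign(perm_es) == sign(es)]
  if (!length(same)) return(NA_real_)
  es / mean(abs(same))
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name description gene1 gene2 ...`.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop_scperf("duplicate gene-set names")
  sets
}

#' Gene-set enrichment metric for one clustering output
#'
#' Gene sets are filtered to sizes strictly between `min_size` and
#' `max_size` (more than 10 and fewer than 500 genes by default).  For
#' every cluster, genes are ranked by one-vs-rest log2 fold change
#' ([find_markers()]), the absolute NES is computed per retained set and
#' aggregated within the cluster (mean by default), and the metric is the
#' mean over clusters.
#'
#' @param counts genes x cells raw counts (or `synthetic_dataset`).
#' @param clustering a `clustering_result`.
#' @param sets named list of gene sets.
#' @param n_perm permutations for the NES.
#' @param min_size,max_size exclusive size bounds for retained sets.
#' @param aggregate within-cluster aggregation of |NES| over sets.
#' @param seed integer seed.
#' @return mean-over-clusters |NES|; `NA` when k = 1; error when no set
#'   passes the size filter.
#' @export
gsea_metric <- function(counts, clustering, sets, n_perm = 1000,
                        min_size = 10, max_size = 500,
                        aggregate = c("mean", "max"), seed = 1L) {
  aggregate <- match.arg(aggregate)
  sizes <- lengths(sets)
  sets <- sets[sizes > min_size & sizes < max_size]
  if (!length(sets))
    stop_scperf("no gene sets within the size bounds (", min_size, ", ",
                max_size, ")")
  if (is.na(clustering$k) || clustering$k < 2) return(NA_real_)
  m <- get_counts(counts)[, clustering$kept_cell_ids, drop = FALSE]
  norm <- normalize_counts(m, "lognorm")
  markers <- find_markers(norm, clustering$labels)
  ## per-set seeds shared across clusters so the metric is invariant to
  ## cluster relabeling
  seeds <- split_seed(seed, length(sets))
  per_cluster <- vapply(seq_along(markers), function(ci) {
    stats <- markers[[ci]]
    nes <- vapply(seq_along(sets), function(si)
      gsea_nes(stats, sets[[si]], n_perm = n_perm,
               seed = seeds[si]), numeric(1))
    nes <- abs(nes[!is.na(nes)])
    if (!length(nes)) return(NA_real_)
    if (aggregate == "mean") mean(nes) else max(nes)
  }, numeric(1))
  mean(per_cluster, na.rm = TRUE)
}
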