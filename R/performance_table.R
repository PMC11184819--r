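#' Score clustering results into a performance table
#'
#' Computes the four raw metrics — Calinski-Harabasz (`CH`), negated
#' Davies-Bouldin (`DB_neg`), mean silhouette (`SIL`) and, when gene sets
#' are supplied, the GSEA score (`GSEA`) — for every clustering result.
#' Purity metrics are evaluated on the log1p counts of the kept cells
#' restricted to the 500 most variable genes ([purity_input()]).  Results
#' with k = 1 (or failed runs) yield `NA` metrics, to be imputed later.
#'
#' @param datasets named list of datasets (ids matching the results).
#' @param results list of `clustering_result` objects from [run_grid()].
#' @param sets optional gene-set list enabling the GSEA metric.
#' @param n_perm GSEA permutations.
#' @param seed integer seed (GSEA permutations).
#' @return data frame with columns `dataset_id`, `pipeline_id`, `k`, and
#'   one raw column per metric.
#' @export
score_clusterings <- function(datasets, results, sets = NULL, n_perm = 200,
                              seed = 1L) {
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    base <- data.frame(dataset_id = r$dataset_id, pipeline_id = r$pipeline_id,
                       k = r$k, CH = NA_real_, DB_neg = NA_real_,
                       SIL = NA_real_, stringsAsFactors = FALSE)
    if (!is.null(sets)) base$GSEA <- NA_real_
    if (!is.null(r$error) || is.na(r$k) || r$k < 2) return(base)
    X <- purity_input(datasets[[r$dataset_id]], r)
    lab <- r$labels[rownames(X)]
    base$CH <- tryCatch(calinski_harabasz(X, lab), error = function(e) NA_real_)
    base$DB_neg <- davies_bouldin_neg(X, lab)
    base$SIL <- silhouette_mean(X, lab)
    if (!is.null(sets))
      base$GSEA <- tryCatch(
        gsea_metric(datasets[[r$dataset_id]], r, sets, n_perm = n_perm,
                    seed = seed + i),
        error = function(e) NA_real_)
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

metric_columns <- function(table) {
  intersect(c("CH", "DB_neg", "SIL", "GSEA"), names(table))
}

#' Z-score metrics within each dataset
#'
#' Each metric column is centered and scaled (sample standard deviation) to
#' mean 0, variance 1 within every dataset, over its non-missing rows;
#' missing values stay missing.  Adds `<metric>_scaled` columns.
#'
#' @param table a [score_clusterings()] table (or any table with
#'   `dataset_id` and metric columns).
#' @param metrics metric columns to scale.
#' @return the table with scaled columns appended.
#' @export
scale_within_dataset <- function(table, metrics = metric_columns(table)) {
  for (m in metrics) {
    scaled <- rep(NA_real_, nrow(table))
    for (d in unique(table$dataset_id)) {
      idx <- table$dataset_id == d & !is.na(table[[m]]) &
        is.finite(table[[m]])
      if (sum(idx) < 2) next
      x <- table[[m]][idx]
      s <- sd(x)
      if (s == 0) {
        warning(sprintf("zero variance for %s in dataset %s; scaled to 0", m, d))
        scaled[idx] <- 0
      } else {
        scaled[idx] <- (x - mean(x)) / s
      }
    }
    table[[paste0(m, "_scaled")]] <- scaled
  }
  table
}

#' Remove the cluster-number trend from scaled metrics
#'
#' Cluster-purity metrics vary systematically with the number of clusters
#' k, which pipelines control through the resolution parameter.  Per
#' dataset, a local regression (tricube weights, degree 2, span 0.75) of
#' the scaled metric on k is fitted and its residuals become the corrected
#' metric, removing the k-confound while preserving k-independent pipeline
#' effects.  Adds `<metric>_corrected` columns.
#'
#' @param table a table with `<metric>_scaled`, `dataset_id`, `k`.
#' @param metrics metrics to correct (defaults to the purity metrics; the
#'   GSEA column can be included explicitly).
#' @param span loess span.
#' @return the table with corrected columns appended.
#' @export
correct_for_k <- function(table, metrics = intersect(c("CH", "DB_neg", "SIL"),
                                                     metric_columns(table)),
                          span = 0.75) {
  for (m in metrics) {
    sc <- paste0(m, "_scaled")
    if (!sc %in% names(table)) stop_scperf("scale_within_dataset first: no ", sc)
    corrected <- rep(NA_real_, nrow(table))
    for (d in unique(table$dataset_id)) {
      idx <- which(table$dataset_id == d & !is.na(table[[sc]]))
      if (!length(idx)) next
      kk <- table$k[idx]
      y <- table[[sc]][idx]
      if (length(unique(kk)) < 2) {
        warning(sprintf("k constant in dataset %s; %s centered only", d, m))
        corrected[idx] <- y - mean(y)
      } else {
        corrected[idx] <- local_fit_residuals(kk, y, span = span, degree = 2)
      }
    }
    table[[paste0(m, "_corrected")]] <- corrected
  }
  table
}

#' Impute missing metric values with per-dataset medians
#'
#' Missing entries (clusterings with a single cluster, failed runs) are
#' replaced by the per-dataset median of the corrected (or, for metrics
#' without a corrected column, scaled) value; an `<metric>_imputed` flag
#' records which rows were filled.
#'
#' @param table a scaled (and, for purity metrics, corrected) table.
#' @param metrics metrics to impute.
#' @return the table with imputed values and flag columns.
#' @export
impute_missing <- function(table, metrics = metric_columns(table)) {
  for (m in metrics) {
    col <- if (paste0(m, "_corrected") %in% names(table))
      paste0(m, "_corrected") else paste0(m, "_scaled")
    if (!col %in% names(table)) stop_scperf("no scaled/corrected column for ", m)
    flag <- is.na(table[[col]])
    for (d in unique(table$dataset_id)) {
      idx <- table$dataset_id == d
      vals <- table[[col]][idx]
      if (all(is.na(vals)))
        stop_scperf("dataset ", d, " has no observed values for ", m)
      med <- median(vals, na.rm = TRUE)
      table[[col]][idx & is.na(table[[col]])] <- med
    }
    table[[paste0(m, "_imputed")]] <- flag
  }
  table
}

#' Full metric post-processing
#'
#' Convenience wrapper: scale within dataset, correct the purity metrics
#' for cluster number (optionally GSEA too), impute missing values.
#'
#' @param table raw [score_clusterings()] table.
#' @param correct_gsea also loess-correct the GSEA column.
#' @return finalized performance table.
#' @export
finalize_performance_table <- function(table, correct_gsea = FALSE) {
  table <- scale_within_dataset(table)
  purity <- intersect(c("CH", "DB_neg", "SIL"), metric_columns(table))
  to_correct <- if (correct_gsea) metric_columns(table) else purity
  table <- correct_for_k(table, metrics = to_correct)
  impute_missing(table)
}

#' Column holding the final (corrected or scaled) value of a metric
#' @param table performance table.
#' @param metric metric name.
#' @return column name.
#' @export
final_metric_column <- function(table, metric) {
  if (paste0(metric, "_corrected") %in% names(table))
    paste0(metric, "_corrected") else paste0(metric, "_scaled")
}
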