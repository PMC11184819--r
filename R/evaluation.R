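#' Per-dataset correlation between predictions and observed metric
#'
#' For each test dataset, the Pearson correlation between the model's
#' predictions and the observed (corrected) metric values over that
#' dataset's pipelines.
#'
#' @param predictions numeric predictions aligned with `observed`.
#' @param observed observed metric values.
#' @param dataset_id dataset id per row.
#' @param min_rows minimum pipelines per dataset (default 3).
#' @return data frame with `dataset_id`, `r`, `n`; `r` is `NA` when
#'   predictions or observations are constant within the dataset.
#' @export
per_dataset_correlation <- function(predictions, observed, dataset_id,
                                    min_rows = 3) {
  stopifnot(length(predictions) == length(observed),
            length(observed) == length(dataset_id))
  ids <- unique(dataset_id)
  rows <- lapply(ids, function(d) {
    idx <- dataset_id == d
    n <- sum(idx)
    r <- if (n < min_rows || sd(predictions[idx]) == 0 ||
             sd(observed[idx]) == 0) NA_real_
      else cor(predictions[idx], observed[idx])
    data.frame(dataset_id = d, r = r, n = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-sided Wilcoxon signed-rank test of correlations against zero
#'
#' Tests whether a sample of per-dataset correlations is centered above 0
#' (alternative: greater).  The exact null distribution is used for small
#' samples without ties or zeros; otherwise the normal approximation with
#' continuity correction.
#'
#' @param correlations numeric vector (NAs dropped); needs >= 5 values.
#' @return one-sided p-value.
#' @export
wilcoxon_vs_zero <- function(correlations) {
  x <- correlations[!is.na(correlations)]
  if (length(x) < 5) stop_scperf("need at least 5 correlations")
  if (all(x == 0)) return(1)
  suppressWarnings(
    wilcox.test(x, mu = 0, alternative = "greater", correct = TRUE)$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = "BH")
}

#' Correlate predictions with ARI against reference labels
#'
#' For every dataset holding reference labels, computes the ARI between
#' each pipeline's clustering and the reference (restricted to the kept
#' cells), then the Pearson correlation of the model's predictions with
#' those ARIs across pipelines.
#'
#' @param predictions numeric predictions aligned with `dataset_id` /
#'   `pipeline_id`.
#' @param dataset_id,pipeline_id row keys for the predictions.
#' @param results named list of `clustering_result`s
#'   (`"<dataset>.<pipeline>"` keys, as from [run_grid()]).
#' @param reference_labels named list (by dataset id) of named label
#'   vectors.
#' @return data frame with `dataset_id`, `r` (NA when ARI is constant),
#'   `n`, restricted to labeled datasets.
#' @export
ari_agreement <- function(predictions, dataset_id, pipeline_id, results,
                          reference_labels) {
  rows <- lapply(names(reference_labels), function(d) {
    idx <- which(dataset_id == d)
    if (!length(idx)) return(NULL)
    ref <- reference_labels[[d]]
    ari <- vapply(idx, function(i) {
      r <- results[[paste(d, pipeline_id[i], sep = ".")]]
      if (is.null(r) || !is.null(r$error) || length(r$kept_cell_ids) < 2)
        return(NA_real_)
      adjusted_rand_index(r$labels, ref[names(r$labels)])
    }, numeric(1))
    ok <- !is.na(ari)
    r <- if (sum(ok) < 3 || sd(ari[ok]) == 0 || sd(predictions[idx][ok]) == 0)
      NA_real_ else cor(predictions[idx][ok], ari[ok])
    data.frame(dataset_id = d, r = r, n = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Which dataset features explain predictive performance?
#'
#' Correlates every dataset feature with the per-dataset predictive
#' performance (itself a correlation) and attaches the two-sided p-value
#' of the correlation t-test, \eqn{t = r\sqrt{(n-2)/(1-r^2)}}.
#'
#' @param performance data frame from [per_dataset_correlation()] (or
#'   [ari_agreement()]).
#' @param features dataset feature table (with `dataset_id`).
#' @param min_n minimum datasets required (default 5).
#' @return data frame with `feature`, `r`, `p`; constant features are
#'   skipped with a note in the `note` attribute.
#' @export
determinant_analysis <- function(performance, features, min_n = 5) {
  merged <- merge(performance, features, by = "dataset_id")
  merged <- merged[!is.na(merged$r), ]
  if (nrow(merged) < min_n)
    stop_scperf("need at least ", min_n, " test datasets with defined r")
  feats <- setdiff(names(features), "dataset_id")
  skipped <- character(0)
  rows <- lapply(feats, function(f) {
    x <- merged[[f]]
    if (sd(x) == 0) { skipped <<- c(skipped, f); return(NULL) }
    ct <- cor.test(x, merged$r, method = "pearson", alternative = "two.sided")
    data.frame(feature = f, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "note") <- if (length(skipped))
    paste("constant features skipped:", paste(skipped, collapse = ", "))
  out
}

#' Filter determinant reports to features significant in >= 1 model
#'
#' @param reports named list of [determinant_analysis()] data frames (one
#'   per model/metric block).
#' @param alpha significance level (default 0.05).
#' @return combined long data frame (`block`, `feature`, `r`, `p`)
#'   restricted to features with `p < alpha` in at least one block.
#' @export
significant_determinants <- function(reports, alpha = 0.05) {
  long <- do.call(rbind, lapply(names(reports), function(b)
    cbind(block = b, reports[[b]], stringsAsFactors = FALSE)))
  sig <- unique(long$feature[long$p < alpha])
  long[long$feature %in% sig, ]
}

#' Default configuration for the end-to-end synthetic study
#'
#' A desk-scale study: 6 synthetic datasets, a 36-pipeline subgrid
#' (3 filtering x 3 normalization x 2 dimensionalities x 2 resolutions),
#' both meta-model kinds in both feature modes over all four metrics.
#'
#' @return named list of study parameters.
#' @export
default_study_config <- function() {
  list(n_datasets = 6,
       n_genes = 1200,
       ranges = modifyList(default_collection_ranges(),
                           list(n_cells = c(200, 400),
                                n_clusters = c(2, 5))),
       grid = list(filtering = c("default", "stringent", "lenient"),
                   normalization = c("lognorm", "pooling", "pearson"),
                   n_dims = c(10, 20),
                   resolution = c(0.5, 1.0)),
       n_gene_sets = 15,
       gsea_n_perm = 100,
       labeled_frac = 0.4,
       test_frac = 0.34,
       cv_folds = 2,
       metrics = c("CH", "DB_neg", "SIL", "GSEA"),
       model_kinds = c("random_forest", "elastic_net"),
       modes = c("interactions", "pipeline_only"),
       rf_ntree = 100, rf_mtry = NULL, tune = FALSE)
}

#' Run the end-to-end synthetic study
#'
#' Orchestrates the full workflow on synthetic data: generate a dataset
#' collection and gene sets, run the pipeline grid, score all four
#' metrics, scale / k-correct / impute, build dataset features
#' (train-fitted), split dataset-aware, fit meta-models for every
#' kind x mode x metric block, and evaluate per-dataset correlations,
#' signed-rank significance with BH adjustment, ARI agreement on labeled
#' datasets, and determinants of predictive performance.
#'
#' @param config study configuration, see [default_study_config()];
#'   entries override the defaults.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @param verbose print stage progress.
#' @return report bundle: list with `performance_table`, `features`,
#'   `split`, `evaluation` (one block per model/mode/metric),
#'   `significance`, `ari_agreement`, `determinants`, `grid`, `config`.
#' @export
run_full_study <- function(config = list(), seed = 1L, out_dir = NULL,
                           verbose = FALSE) {
  cfg <- modifyList(default_study_config(), config)
  seeds <- split_seed(seed, 6)
  say <- function(...) if (verbose) message(...)

  say("stage 1/6: synthetic collection")
  collection <- generate_dataset_collection(cfg$n_datasets,
                                            ranges = cfg$ranges,
                                            n_genes = cfg$n_genes,
                                            seed = seeds[1])
  sets <- generate_gene_sets(rownames(get_counts(collection[[1]])),
                             n_sets = cfg$n_gene_sets, seed = seeds[2])

  say("stage 2/6: pipeline grid over ", cfg$n_datasets, " datasets")
  grid <- do.call(enumerate_grid, cfg$grid)
  results <- run_grid(collection, grid, seed = seeds[3])

  say("stage 3/6: metric scoring")
  perf <- score_clusterings(collection, results, sets = sets,
                            n_perm = cfg$gsea_n_perm, seed = seeds[4])
  perf <- finalize_performance_table(perf)

  say("stage 4/6: dataset features and split")
  ids <- names(collection)
  n_labeled <- max(1, round(cfg$labeled_frac * floor(cfg$test_frac *
                                                       length(ids))))
  labeled <- withr::with_seed(seeds[5], sample(ids, n_labeled))
  split <- dataset_aware_split(ids, labeled, test_frac = cfg$test_frac,
                               seed = seeds[5])
  feats <- build_dataset_features(collection, split$train,
                                  q = min(20, length(split$train) - 1))
  folds <- dataset_aware_cv_folds(split$train,
                                  k = min(cfg$cv_folds, length(split$train)),
                                  seed = seeds[6])

  say("stage 5/6: meta-models (", length(cfg$model_kinds), " kinds x ",
      length(cfg$modes), " modes x ", length(cfg$metrics), " metrics)")
  test_rows <- perf$dataset_id %in% split$test
  train_rows <- !test_rows
  evaluation <- list()
  for (kind in cfg$model_kinds) for (mode in cfg$modes)
    for (metric in cfg$metrics) {
      block <- paste(kind, mode, metric, sep = ".")
      mk <- if (kind == "random_forest") "tree" else "linear"
      inp_tr <- assemble_features(feats$table, grid, perf[train_rows, ],
                                  metric = metric, mode = mode,
                                  model_kind = mk)
      inp_te <- assemble_features(feats$table, grid, perf[test_rows, ],
                                  metric = metric, mode = mode,
                                  model_kind = mk)
      model <- if (kind == "random_forest") {
        tune_random_forest(inp_tr, folds = if (cfg$tune) folds else NULL,
                           ntree_grid = cfg$rf_ntree,
                           mtry_grid = cfg$rf_mtry, seed = seeds[6])
      } else {
        tune_elastic_net(inp_tr, folds = if (cfg$tune) folds else NULL,
                         seed = seeds[6])
      }
      pred <- predict(model, inp_te)
      pd <- per_dataset_correlation(pred, inp_te$y, inp_te$dataset_id)
      evaluation[[block]] <- list(model = model, per_dataset = pd,
                                  predictions = data.frame(
                                    dataset_id = inp_te$dataset_id,
                                    pipeline_id = inp_te$pipeline_id,
                                    predicted = pred, observed = inp_te$y,
                                    stringsAsFactors = FALSE))
    }

  say("stage 6/6: significance, ARI agreement, determinants")
  signif_tab <- data.frame(
    block = names(evaluation),
    median_r = vapply(evaluation, function(b)
      median(b$per_dataset$r, na.rm = TRUE), numeric(1)),
    p = vapply(evaluation, function(b)
      tryCatch(wilcoxon_vs_zero(b$per_dataset$r), error = function(e) NA_real_),
      numeric(1)),
    stringsAsFactors = FALSE)
  signif_tab$p_adj <- bh_adjust(signif_tab$p)
  rownames(signif_tab) <- NULL

  ref_labels <- lapply(collection[split$labeled],
                       function(d) d$true_labels)
  ari <- lapply(evaluation, function(b)
    ari_agreement(b$predictions$predicted, b$predictions$dataset_id,
                  b$predictions$pipeline_id, results, ref_labels))

  determinants <- tryCatch({
    reps <- lapply(evaluation, function(b)
      determinant_analysis(b$per_dataset, feats$table,
                           min_n = min(5, length(split$test))))
    significant_determinants(reps)
  }, error = function(e) NULL)

  bundle <- list(performance_table = perf, features = feats$table,
                 split = split, evaluation = evaluation,
                 significance = signif_tab, ari_agreement = ari,
                 determinants = determinants, grid = grid,
                 results = results, config = cfg, seed = seed)
  if (!is.null(out_dir)) write_study_outputs(bundle, out_dir)
  bundle
}

#' Write study outputs as CSV / JSON
#'
#' @param bundle a [run_full_study()] bundle.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(performance = file.path(out_dir, "performance_table.csv"),
             features = file.path(out_dir, "dataset_features.csv"),
             significance = file.path(out_dir, "significance.csv"),
             summary = file.path(out_dir, "summary.json"))
  utils::write.csv(bundle$performance_table, paths["performance"],
                   row.names = FALSE)
  utils::write.csv(bundle$features, paths["features"], row.names = FALSE)
  utils::write.csv(bundle$significance, paths["significance"],
                   row.names = FALSE)
  summary <- list(
    seed = bundle$seed,
    n_datasets = length(unique(bundle$performance_table$dataset_id)),
    n_pipelines = nrow(bundle$grid),
    split = bundle$split,
    median_r = lapply(bundle$evaluation, function(b)
      median(b$per_dataset$r, na.rm = TRUE)))
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
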