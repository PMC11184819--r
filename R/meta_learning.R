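#' Encode pipeline parameters as model features
#'
#' Tree models receive the two categorical steps as integer codes plus the
#' two numeric parameters (4 columns); linear models receive full one-hot
#' indicators for the categorical steps plus the numerics (8 columns for
#' the default grid).  Numeric columns are standardized over the grid.
#'
#' @param grid a [enumerate_grid()] data frame.
#' @param encoding `"code"` (tree models) or `"onehot"` (linear models).
#' @return numeric matrix with `pipeline_id` rownames.
#' @export
encode_pipeline_features <- function(grid, encoding = c("code", "onehot")) {
  encoding <- match.arg(encoding)
  zs <- function(x) if (sd(x) == 0) rep(0, length(x)) else (x - mean(x)) / sd(x)
  num <- cbind(n_dims = zs(grid$n_dims), resolution = zs(grid$resolution))
  if (encoding == "code") {
    out <- cbind(filtering = as.numeric(factor(grid$filtering)),
                 normalization = as.numeric(factor(grid$normalization)),
                 num)
  } else {
    oh <- function(x, prefix) {
      lev <- sort(unique(x))
      m <- vapply(lev, function(l) as.numeric(x == l), numeric(length(x)))
      colnames(m) <- paste0(prefix, "_", lev)
      m
    }
    out <- cbind(oh(grid$filtering, "filtering"),
                 oh(grid$normalization, "normalization"), num)
  }
  rownames(out) <- grid$pipeline_id
  out
}

#' Assemble meta-model inputs
#'
#' Joins the dataset feature table, the pipeline grid and a finalized
#' performance table into a design matrix.  Modes:
#' \itemize{
#'  \item `pipeline_only`: pipeline parameters only (4 columns for tree
#'    models), so predictions cannot be dataset-specific.
#'  \item `interactions`: dataset features + pipeline parameters (45
#'    columns for tree models, which learn interactions implicitly); for
#'    linear models, all dataset-feature x pipeline-column products are
#'    appended to the mains.
#' }
#'
#' @param features `table` element of [build_dataset_features()].
#' @param grid a [enumerate_grid()] data frame.
#' @param table finalized performance table.
#' @param metric metric to model (target = its corrected/scaled column).
#' @param mode `"interactions"` or `"pipeline_only"`.
#' @param model_kind `"tree"` or `"linear"` (controls the encoding).
#' @return object of class `model_input`: list with `x` (matrix), `y`,
#'   `dataset_id`, `pipeline_id`, `metric`, `mode`, `model_kind`.
#' @export
assemble_features <- function(features, grid, table, metric = "CH",
                              mode = c("interactions", "pipeline_only"),
                              model_kind = c("tree", "linear")) {
  mode <- match.arg(mode); model_kind <- match.arg(model_kind)
  target_col <- final_metric_column(table, metric)
  if (!target_col %in% names(table)) stop_scperf("no column ", target_col)
  pf <- encode_pipeline_features(grid,
                                 if (model_kind == "tree") "code" else "onehot")
  if (!all(table$pipeline_id %in% rownames(pf)))
    stop_scperf("unknown pipeline id in performance table")
  Z <- pf[table$pipeline_id, , drop = FALSE]
  if (mode == "pipeline_only") {
    x <- Z
  } else {
    fmat <- as.matrix(features[, setdiff(names(features), "dataset_id"),
                               drop = FALSE])
    rownames(fmat) <- features$dataset_id
    if (!all(table$dataset_id %in% rownames(fmat)))
      stop_scperf("unknown dataset id in performance table")
    X <- fmat[table$dataset_id, , drop = FALSE]
    x <- cbind(X, Z)
    if (model_kind == "linear") {
      inter <- matrix(NA_real_, nrow(x), ncol(X) * ncol(Z))
      cn <- character(ncol(inter))
      idx <- 0
      for (i in seq_len(ncol(X))) for (j in seq_len(ncol(Z))) {
        idx <- idx + 1
        inter[, idx] <- X[, i] * Z[, j]
        cn[idx] <- paste(colnames(X)[i], colnames(Z)[j], sep = ":")
      }
      colnames(inter) <- cn
      x <- cbind(x, inter)
    }
  }
  y <- table[[target_col]]
  keep <- !is.na(y)
  structure(list(x = x[keep, , drop = FALSE], y = y[keep],
                 dataset_id = table$dataset_id[keep],
                 pipeline_id = table$pipeline_id[keep],
                 metric = metric, mode = mode, model_kind = model_kind),
            class = "model_input")
}

#' Dataset-aware train/test split
#'
#' Every dataset's rows land entirely in train or test.  Labeled datasets
#' (those with reference cell-type labels) are forced into the test set so
#' ARI-based evaluation stays possible; the rest of the test set is filled
#' at random to `floor(test_frac * n)` datasets.
#'
#' @param dataset_ids all dataset ids.
#' @param labeled_ids ids forced into the test set.
#' @param test_frac test fraction (default 0.3).
#' @param seed integer seed.
#' @return list with `train`, `test`, `labeled`.
#' @export
dataset_aware_split <- function(dataset_ids, labeled_ids = character(0),
                                test_frac = 0.3, seed = 1L) {
  stopifnot(all(labeled_ids %in% dataset_ids))
  n_test <- floor(test_frac * length(dataset_ids))
  if (length(labeled_ids) > n_test)
    stop_scperf("more labeled datasets (", length(labeled_ids),
                ") than test slots (", n_test, ")")
  pool <- setdiff(dataset_ids, labeled_ids)
  fill <- withr::with_seed(seed, sample(pool, n_test - length(labeled_ids)))
  test <- c(labeled_ids, fill)
  list(train = setdiff(dataset_ids, test), test = test,
       labeled = labeled_ids)
}

#' Dataset-aware cross-validation folds
#'
#' Balanced random partition of the train dataset ids into `k` folds
#' (fold sizes differ by at most one); every dataset appears in exactly
#' one fold, so no dataset spans folds.
#'
#' @param train_ids train dataset ids.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return list of `k` character vectors.
#' @export
dataset_aware_cv_folds <- function(train_ids, k = 10, seed = 1L) {
  if (k > length(train_ids))
    stop_scperf("k exceeds the number of train datasets")
  shuffled <- withr::with_seed(seed, sample(train_ids))
  split(shuffled, rep(seq_len(k), length.out = length(shuffled)))
}

subset_input <- function(input, rows) {
  structure(list(x = input$x[rows, , drop = FALSE], y = input$y[rows],
                 dataset_id = input$dataset_id[rows],
                 pipeline_id = input$pipeline_id[rows],
                 metric = input$metric, mode = input$mode,
                 model_kind = input$model_kind),
            class = "model_input")
}

cv_rmse <- function(input, folds, fit_fun, predict_fun) {
  errs <- lapply(folds, function(fold) {
    hold <- input$dataset_id %in% fold
    if (!any(hold) || all(hold)) return(NULL)
    fit <- fit_fun(subset_input(input, !hold))
    pred <- predict_fun(fit, input$x[hold, , drop = FALSE])
    (pred - input$y[hold])^2
  })
  sqrt(mean(unlist(errs)))
}

#' Tune and fit a random-forest meta-model
#'
#' Grid search over `ntree` in {100, 300, 500} and an `mtry` subgrid
#' {1, ceil(p/3), ceil(p/2), p} (full range optional via `mtry_grid`),
#' scored by dataset-aware cross-validated RMSE; the best point is refitted
#' on the full train input.  With `folds = NULL` the first grid point is
#' fitted directly without tuning.
#'
#' @param input a [assemble_features()] input (train rows).
#' @param folds [dataset_aware_cv_folds()] folds, or `NULL`.
#' @param ntree_grid,mtry_grid hyperparameter grids.
#' @param seed integer seed for the forest.
#' @return object of class `tuned_model`.
#' @export
tune_random_forest <- function(input, folds,
                               ntree_grid = c(100, 300, 500),
                               mtry_grid = NULL, seed = 1L) {
  p <- ncol(input$x)
  if (var(input$y) == 0) stop_scperf("target has zero variance")
  mtry_grid <- unique(pmin(mtry_grid %||%
                             c(1, ceiling(p / 3), ceiling(p / 2), p), p))
  grid <- expand.grid(ntree = ntree_grid, mtry = mtry_grid)
  fit_fun <- function(par) function(inp)
    withr::with_seed(seed, randomForest::randomForest(
      x = inp$x, y = inp$y, ntree = par$ntree, mtry = par$mtry))
  if (is.null(folds)) {
    grid$cv_rmse <- NA_real_
    best <- 1L
  } else {
    grid$cv_rmse <- vapply(seq_len(nrow(grid)), function(i)
      cv_rmse(input, folds, fit_fun(grid[i, ]),
              function(f, x) predict(f, x)), numeric(1))
    best <- which.min(grid$cv_rmse)
  }
  fit <- fit_fun(grid[best, ])(input)
  structure(list(kind = "random_forest", mode = input$mode,
                 metric = input$metric, fit = fit,
                 hyperparameters = as.list(grid[best, c("ntree", "mtry")]),
                 cv = grid, feature_names = colnames(input$x)),
            class = "tuned_model")
}

#' Tune and fit an elastic-net meta-model
#'
#' Coordinate-descent elastic net over alpha in {0.10, 0.55, 1.00} and
#' lambda in {0.001, 0.01, 0.1} (9 grid points), scored by dataset-aware
#' cross-validated RMSE and refitted on the full train input.
#'
#' @inheritParams tune_random_forest
#' @param alpha_grid,lambda_grid hyperparameter grids.
#' @return object of class `tuned_model`.
#' @export
tune_elastic_net <- function(input, folds,
                             alpha_grid = c(0.10, 0.55, 1.00),
                             lambda_grid = c(0.001, 0.01, 0.1), seed = 1L) {
  if (any(!is.finite(input$x)) || any(!is.finite(input$y)))
    stop_scperf("non-finite values in model input")
  grid <- expand.grid(alpha = alpha_grid, lambda = lambda_grid)
  fit_fun <- function(par) function(inp)
    glmnet::glmnet(inp$x, inp$y, alpha = par$alpha,
                   lambda = sort(unique(c(par$lambda, lambda_grid)),
                                 decreasing = TRUE))
  pred_fun <- function(par) function(f, x)
    drop(predict(f, x, s = par$lambda))
  if (is.null(folds)) {
    grid$cv_rmse <- NA_real_
    best <- 1L
  } else {
    grid$cv_rmse <- vapply(seq_len(nrow(grid)), function(i)
      cv_rmse(input, folds, fit_fun(grid[i, ]), pred_fun(grid[i, ])),
      numeric(1))
    best <- which.min(grid$cv_rmse)
  }
  fit <- fit_fun(grid[best, ])(input)
  structure(list(kind = "elastic_net", mode = input$mode,
                 metric = input$metric, fit = fit,
                 hyperparameters = as.list(grid[best, c("alpha", "lambda")]),
                 cv = grid, feature_names = colnames(input$x)),
            class = "tuned_model")
}

#' Predict with a tuned meta-model
#'
#' @param object a `tuned_model`.
#' @param input a `model_input` (or bare feature matrix) with the training
#'   column layout.
#' @param ... unused.
#' @return numeric predictions, one per row, in row order.
#' @export
predict.tuned_model <- function(object, input, ...) {
  x <- if (inherits(input, "model_input")) input$x else as.matrix(input)
  if (!identical(colnames(x), object$feature_names))
    stop_scperf("feature layout does not match the trained model")
  if (object$kind == "random_forest") {
    unname(predict(object$fit, x))
  } else {
    unname(drop(predict(object$fit, x, s = object$hyperparameters$lambda)))
  }
}

#' Feature importance of a tuned meta-model
#'
#' Random forests report the total decrease in node impurity
#' (IncNodePurity) per feature; elastic nets report absolute coefficient
#' values at the selected lambda.
#'
#' @param model a `tuned_model`.
#' @return named non-negative numeric vector.
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "tuned_model") || is.null(model$fit))
    stop_scperf("model is not a fitted tuned_model")
  if (model$kind == "random_forest") {
    imp <- model$fit$importance[, "IncNodePurity"]
    names(imp) <- rownames(model$fit$importance)
    imp
  } else {
    co <- coef(model$fit, s = model$hyperparameters$lambda)
    out <- abs(as.numeric(co))[-1]
    names(out) <- rownames(co)[-1]
    out
  }
}
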