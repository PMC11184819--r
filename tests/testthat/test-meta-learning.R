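fake_features <- function(n_datasets = 10, n_feats = 6, seed = 1) {
  X <- withr::with_seed(seed, matrix(rnorm(n_datasets * n_feats),
                                     n_datasets, n_feats))
  colnames(X) <- paste0("f", seq_len(n_feats))
  data.frame(dataset_id = sprintf("D%02d", seq_len(n_datasets)), X,
             stringsAsFactors = FALSE)
}

fake_perf <- function(features, grid, seed = 2, noise = 0.1) {
  tab <- expand.grid(pipeline_id = grid$pipeline_id,
                     dataset_id = features$dataset_id,
                     stringsAsFactors = FALSE)[, 2:1]
  tab$k <- 3
  tab$CH <- NA_real_
  tab$CH_corrected <- withr::with_seed(seed, rnorm(nrow(tab), 0, 1))
  tab
}

test_that("feature assembly produces the documented column counts", {
  grid <- enumerate_grid()
  feats <- fake_features(6, 41)
  perf <- fake_perf(feats, grid)
  tree_int <- assemble_features(feats, grid, perf, mode = "interactions",
                                model_kind = "tree")
  expect_equal(ncol(tree_int$x), 45)
  tree_po <- assemble_features(feats, grid, perf, mode = "pipeline_only",
                               model_kind = "tree")
  expect_equal(ncol(tree_po$x), 4)
  lin_int <- assemble_features(feats, grid, perf, mode = "interactions",
                               model_kind = "linear")
  expect_equal(ncol(lin_int$x), 41 + 8 + 41 * 8)
  expect_equal(nrow(tree_int$x), nrow(perf))

  bad <- perf
  bad$pipeline_id[1] <- "P999"
  expect_error(assemble_features(feats, grid, bad), "unknown pipeline id")
})

test_that("dataset-aware split forces labeled datasets into a 70/30 test set", {
  ids <- sprintf("D%02d", 1:86)
  labeled <- sprintf("D%02d", 1:16)
  sp <- dataset_aware_split(ids, labeled, test_frac = 0.3, seed = 1)
  expect_length(sp$test, 25)
  expect_length(sp$train, 61)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  for (s in 1:100) {
    sp_s <- dataset_aware_split(ids, labeled, seed = s)
    expect_true(all(labeled %in% sp_s$test))
  }
  expect_length(dataset_aware_split(sprintf("D%d", 1:10),
                                    test_frac = 0.3, seed = 2)$test, 3)
  expect_error(dataset_aware_split(ids[1:20], labeled, test_frac = 0.3),
               "labeled")
})

test_that("CV folds partition train datasets with balanced sizes", {
  train <- sprintf("D%02d", 1:61)
  folds <- dataset_aware_cv_folds(train, k = 10, seed = 3)
  expect_length(folds, 10)
  expect_setequal(sort(lengths(folds)), c(rep(6, 9), 7))
  expect_setequal(unlist(folds), train)          # each id in exactly one fold
  expect_equal(sum(lengths(folds)), 61)
  expect_identical(folds, dataset_aware_cv_folds(train, k = 10, seed = 3))
  expect_error(dataset_aware_cv_folds(train[1:5], k = 10), "exceeds")
})

planted_input <- function(n_datasets = 12, n_pipe = 20, seed = 5,
                          noise = 0) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n_datasets * n_pipe * 5), n_datasets * n_pipe, 5)
    colnames(x) <- paste0("f", 1:5)
    y <- ifelse(x[, 1] > 0, 2, -2) + rnorm(nrow(x), 0, noise)
    structure(list(x = x, y = y,
                   dataset_id = rep(sprintf("D%02d", seq_len(n_datasets)),
                                    each = n_pipe),
                   pipeline_id = rep(sprintf("P%03d", seq_len(n_pipe)),
                                     n_datasets),
                   metric = "CH", mode = "interactions",
                   model_kind = "tree"),
              class = "model_input")
  })
}

test_that("random-forest tuning recovers a planted threshold function", {
  input <- planted_input()
  folds <- dataset_aware_cv_folds(unique(input$dataset_id), k = 3, seed = 1)
  model <- tune_random_forest(input, folds, ntree_grid = c(50, 100),
                              mtry_grid = c(1, 2, 5), seed = 9)
  expect_equal(nrow(model$cv), 2 * 3)
  expect_equal(min(model$cv$cv_rmse),
               model$cv$cv_rmse[model$cv$ntree == model$hyperparameters$ntree &
                                  model$cv$mtry == model$hyperparameters$mtry])
  expect_lt(min(model$cv$cv_rmse), 0.2 * sd(input$y))
  pred <- predict(model, input)
  expect_lt(sqrt(mean((pred - input$y)^2)), 0.1 * sd(input$y))
  expect_equal(names(which.max(feature_importance(model))), "f1")
  expect_true(all(feature_importance(model) >= 0))
  flat <- input; flat$y <- rep(1, length(flat$y))
  expect_error(tune_random_forest(flat, folds), "zero variance")
})

test_that("elastic-net tuning evaluates 9 points and recovers sparse signal", {
  withr::with_seed(11, {
    x <- matrix(rnorm(300 * 8), 300, 8)
    colnames(x) <- paste0("f", 1:8)
    y <- 2 * x[, 1] - 3 * x[, 5] + rnorm(300, 0, 0.1)
  })
  input <- structure(list(x = x, y = y,
                          dataset_id = rep(sprintf("D%02d", 1:10), each = 30),
                          pipeline_id = rep(sprintf("P%03d", 1:30), 10),
                          metric = "CH", mode = "interactions",
                          model_kind = "linear"),
                     class = "model_input")
  folds <- dataset_aware_cv_folds(unique(input$dataset_id), k = 3, seed = 2)
  model <- tune_elastic_net(input, folds, seed = 3)
  expect_equal(nrow(model$cv), 9)
  imp <- feature_importance(model)
  expect_setequal(names(sort(imp, decreasing = TRUE))[1:2], c("f1", "f5"))
  expect_true(all(imp[c("f1", "f5")] > 0))

  # a huge penalty shrinks every coefficient to zero: intercept-only fit
  big <- tune_elastic_net(input, folds = NULL, alpha_grid = 1,
                          lambda_grid = 1e6)
  pred <- predict(big, input)
  expect_lt(diff(range(pred)), 1e-8)
  expect_equal(pred[1], mean(y), tolerance = 1e-6)
})

test_that("predictions follow row order and respect the feature layout", {
  input <- planted_input(n_datasets = 6, n_pipe = 10)
  folds <- dataset_aware_cv_folds(unique(input$dataset_id), k = 2, seed = 1)
  model <- tune_random_forest(input, folds = NULL, ntree_grid = 50,
                              mtry_grid = 2, seed = 1)
  pred <- predict(model, input)
  perm <- sample(length(pred))
  input_perm <- input
  input_perm$x <- input$x[perm, ]
  expect_equal(predict(model, input_perm), pred[perm], tolerance = 1e-12)
  wrong <- input
  colnames(wrong$x) <- paste0("g", 1:5)
  expect_error(predict(model, wrong), "feature layout")

  const <- input
  const$x[] <- 1
  model_c <- tune_random_forest(const, folds = NULL, ntree_grid = 50,
                                mtry_grid = 1, seed = 1)
  expect_lt(diff(range(predict(model_c, const))), 1e-8)
})
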