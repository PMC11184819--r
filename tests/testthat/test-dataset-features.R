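test_that("dataset QC summary has exactly 21 named statistics", {
  d <- separable_dataset(n_cells = 60, n_genes = 200, k = 2, seed = 61)
  qc <- compute_cell_qc(d)
  s <- summarize_dataset_qc(qc, d)
  expect_length(s, 21)
  expect_identical(names(s), dataset_qc_feature_names())
  props <- s[c("median_pct_mito", "frac_cells_high_mito", "sparsity",
               "median_prop_genes_detected", "median_coding_prop",
               "frac_genes_coding")]
  expect_true(all(props >= 0 & props <= 1))
})

test_that("QC summary matches hand computation and scale equivariance", {
  m <- matrix(c(10, 20, 40,
                 5, 10, 20), nrow = 2, byrow = TRUE,
              dimnames = list(c("G1", "G2"), c("C1", "C2", "C3")))
  flags <- data.frame(gene_id = c("G1", "G2"), mito = FALSE, coding = TRUE)
  qc <- compute_cell_qc(m, flags)
  s <- summarize_dataset_qc(qc, m, flags)
  expect_equal(unname(s["median_log10_total_counts"]), log10(30))
  expect_equal(unname(s["log10_n_cells"]), log10(3))

  s2 <- summarize_dataset_qc(compute_cell_qc(2 * m, flags), 2 * m, flags)
  expect_equal(unname(s2["median_log10_total_counts"]),
               unname(s["median_log10_total_counts"]) + log10(2))
  expect_equal(s2["median_pct_top_20"], s["median_pct_top_20"])
  expect_equal(s2["median_pct_mito"], s["median_pct_mito"])

  # all cells identical: MAD fields are 0
  mm <- matrix(rep(c(3, 7), 4), nrow = 2,
               dimnames = list(c("G1", "G2"), paste0("C", 1:4)))
  s3 <- summarize_dataset_qc(compute_cell_qc(mm, flags), mm, flags)
  expect_equal(unname(s3["mad_log10_total_counts"]), 0)
  expect_equal(unname(s3["cv_libsize"]), 0)
})

test_that("mean-expression matrix averages raw counts per dataset", {
  mk <- function(vals) {
    m <- matrix(vals, nrow = 2,
                dimnames = list(c("G1", "G2"), paste0("C", seq_len(length(vals) / 2))))
    Matrix::Matrix(m, sparse = TRUE)
  }
  coll <- list(D1 = mk(c(5, 1, 5, 3)), D2 = mk(c(0, 2, 4, 6)))
  me <- mean_expression_matrix(coll)
  expect_equal(dim(me), c(2, 2))
  expect_equal(me["D1", ], c(G1 = 5, G2 = 2))
  expect_equal(me["D2", ], c(G1 = 2, G2 = 4))
})

test_that("closed-form PPCA recovers noiseless low-rank data", {
  set.seed(71)
  Z <- matrix(rnorm(30 * 3), 30, 3)
  W0 <- matrix(rnorm(50 * 3), 50, 3)
  X <- Z %*% t(W0) + 2
  model <- suppressWarnings(fit_ppca(X, q = 3))
  scores <- transform_ppca(model, X)
  recon <- scores %*% t(model$W) + rep(model$mu, each = 30)
  expect_lt(max(abs(recon - X)), 1e-8)
  expect_equal(model$sigma2, 0)
})

test_that("PPCA noise variance equals the mean of trailing eigenvalues", {
  set.seed(72)
  X <- matrix(rnorm(40 * 25), 40, 25) %*% diag(seq(3, 0.2, length.out = 25))
  q <- 5
  model <- fit_ppca(X, q = q)
  # independent oracle: eigendecomposition of the ML covariance
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc) / nrow(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(model$sigma2, mean(ev[(q + 1):25]), tolerance = 1e-8)
  # score subspace coincides with standard PCA as sigma^2 -> 0
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  Zhat <- transform_ppca(model, X)
  cc <- svd(cor(Zhat, pc$x[, 1:q]))$d   # principal angles via can. corr.
  expect_lt(max(abs(cc - 1)), 1e-6)
  expect_error(fit_ppca(X[1:4, ], q = 5), "q \\+ 1")
})

test_that("transforming the train mean gives zero scores and is reusable", {
  set.seed(73)
  X <- matrix(rnorm(30 * 20), 30, 20)
  model <- fit_ppca(X, q = 4)
  z_mean <- transform_ppca(model, matrix(model$mu, nrow = 1))
  expect_lt(max(abs(z_mean)), 1e-10)
  # a test row equal to a train row gets identical scores
  Ztr <- transform_ppca(model, X)
  Zte <- transform_ppca(model, X[7, , drop = FALSE])
  expect_equal(unname(Zte[1, ]), unname(Ztr[7, ]), tolerance = 1e-12)
  expect_error(transform_ppca(model, X[, 1:5]), "gene universe")
})

test_that("feature scaling is fitted on the train block only (no leakage)", {
  tab <- data.frame(dataset_id = c("A", "B", "C"), f = c(1, 3, 5))
  out <- scale_features(tab, train_ids = c("A", "B"))
  expect_equal(out$table$f, (c(1, 3, 5) - 2) / sd(c(1, 3)))
  expect_equal(unname(out$center["f"]), 2)

  # refitting PPCA with test rows included changes the test scores;
  # the stored train model must be reused instead
  set.seed(74)
  X <- matrix(rnorm(25 * 30), 25, 30)
  train <- 1:18; test <- 19:25
  m_train <- fit_ppca(X[train, ], q = 3)
  z1 <- transform_ppca(m_train, X[test, , drop = FALSE])
  z2 <- transform_ppca(m_train, X[test, , drop = FALSE])
  expect_identical(z1, z2)
  m_leaky <- fit_ppca(X, q = 3)
  z_leak <- transform_ppca(m_leaky, X[test, , drop = FALSE])
  expect_gt(max(abs(abs(z_leak) - abs(z1))), 1e-6)
})

test_that("the assembled feature table has 41 dataset features", {
  coll <- generate_dataset_collection(
    8, ranges = modifyList(default_collection_ranges(),
                           list(n_cells = c(40, 80), n_clusters = c(2, 3))),
    n_genes = 150, seed = 81)
  feats <- suppressWarnings(
    build_dataset_features(coll, train_ids = names(coll)[1:6], q = 5))
  expect_equal(ncol(feats$table) - 1, 21 + 5)
  tr <- feats$table[feats$table$dataset_id %in% names(coll)[1:6], ]
  num <- vapply(tr[-1], mean, numeric(1))
  expect_lt(max(abs(num)), 1e-10)
})
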