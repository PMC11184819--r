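test_that("generator is deterministic and validates its configuration", {
  cfg <- synth_config(n_cells = 80, n_genes = 150, n_clusters = 3, seed = 5)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(as.matrix(d1$counts), as.matrix(d2$counts))
  expect_identical(d1$true_labels, d2$true_labels)
  expect_length(d1$true_labels, 80)
  expect_true(all(d1$counts@x >= 0))
  expect_true(all(d1$counts@x == round(d1$counts@x)))

  expect_error(synth_config(n_cells = 5, n_clusters = 10), "K > n_cells")
  expect_error(synth_config(cluster_props = c(0.5, 0.4), n_clusters = 2),
               "sum to 1")
  expect_error(synth_config(nb_dispersion = 0), "theta")
  expect_error(synth_config(de_prob = 1.5), "de_prob")
})

test_that("K = 1 with no DE gives one shared expression profile", {
  cfg <- synth_config(n_cells = 50, n_genes = 100, n_clusters = 1,
                      de_prob = 0, seed = 2)
  d <- generate_dataset(cfg)
  expect_true(all(d$true_labels == 1))
})

test_that("counts follow the NB mean-variance law and the Poisson limit", {
  # moment recovery at theta = 2: gene-wise var ~ mu + mu^2/theta
  cfg <- synth_config(n_cells = 2000, n_genes = 400, n_clusters = 1,
                      de_prob = 0, nb_dispersion = 2,
                      libsize_sd_log = 0, outlier_cell_frac = 0, seed = 3)
  d <- generate_dataset(cfg)
  m <- as.matrix(d$counts)
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  keep <- mu >= 1
  expect_gt(sum(keep), 50)
  rel_err <- abs(v[keep] - (mu[keep] + mu[keep]^2 / 2)) /
    (mu[keep] + mu[keep]^2 / 2)
  expect_lt(median(rel_err), 0.10)

  # theta -> infinity: variance/mean ratio approaches 1 (Poisson)
  cfg2 <- synth_config(n_cells = 2000, n_genes = 200, n_clusters = 1,
                       de_prob = 0, nb_dispersion = 1e6,
                       libsize_sd_log = 0, outlier_cell_frac = 0, seed = 4)
  d2 <- generate_dataset(cfg2)
  m2 <- as.matrix(d2$counts)
  mu2 <- rowMeans(m2)
  v2 <- apply(m2, 1, var)
  keep2 <- mu2 >= 1
  expect_lt(abs(median(v2[keep2] / mu2[keep2]) - 1), 0.1)
})

test_that("planted clusters are separable by nearest centroid", {
  d <- separable_dataset(n_cells = 300, n_genes = 500, k = 3, seed = 9)
  norm <- as.matrix(normalize_counts(d$counts, "lognorm"))
  cent <- vapply(1:3, function(k) rowMeans(norm[, d$true_labels == k]),
                 numeric(nrow(norm)))
  assigned <- apply(norm, 2, function(x) which.min(colSums((cent - x)^2)))
  expect_gt(mean(assigned == d$true_labels), 0.95)
})

test_that("collections span heterogeneous datasets over a shared gene universe", {
  ranges <- modifyList(default_collection_ranges(),
                       list(n_cells = c(40, 120), n_clusters = c(2, 4)))
  coll <- generate_dataset_collection(86, ranges = ranges, n_genes = 200,
                                      seed = 1)
  expect_length(coll, 86)
  expect_true(all(vapply(coll, function(d)
    identical(rownames(d$counts), rownames(coll[[1]]$counts)), logical(1))))
  n_cells <- vapply(coll, function(d) ncol(d$counts), numeric(1))
  expect_gt(length(unique(n_cells)), 10)

  # identical min = max ranges give identical configs
  fixed <- lapply(ranges, function(r) c(r[1], r[1]))
  coll2 <- generate_dataset_collection(3, ranges = fixed, n_genes = 100,
                                       seed = 2)
  cfgs <- lapply(coll2, function(d) d$config[setdiff(names(d$config), "seed")])
  expect_identical(cfgs[[1]], cfgs[[2]])

  # different master seeds give different library-size draws
  c3 <- generate_dataset_collection(2, ranges = ranges, n_genes = 100, seed = 3)
  c4 <- generate_dataset_collection(2, ranges = ranges, n_genes = 100, seed = 4)
  expect_false(identical(Matrix::colSums(c3[[1]]$counts),
                         Matrix::colSums(c4[[1]]$counts)))
  expect_error(generate_dataset_collection(1), "n_datasets")
  expect_error(generate_dataset_collection(3, ranges = list()), "non-empty")
})

test_that("planted performance tables carry the requested interaction structure", {
  X <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(sprintf("D%02d", 1:8), NULL))
  Z <- matrix(rnorm(12 * 3), 12, 3, dimnames = list(sprintf("P%03d", 1:12), NULL))

  # no interactions, no noise: pipeline ranking identical across datasets
  m0 <- planted_performance_model(5, 3, interaction_sd = 0, noise_sd = 0,
                                  seed = 1)
  t0 <- generate_performance_table(m0, X, Z)
  ranks <- vapply(split(t0, t0$dataset_id),
                  function(b) order(b$planted), integer(12))
  expect_true(all(apply(ranks, 1, function(r) length(unique(r)) == 1)))

  # nonzero interactions: at least two datasets prefer different pipelines
  m1 <- planted_performance_model(5, 3, interaction_sd = 3, noise_sd = 0,
                                  seed = 2)
  t1 <- generate_performance_table(m1, X, Z)
  best <- vapply(split(t1, t1$dataset_id),
                 function(b) b$pipeline_id[which.max(b$planted)], character(1))
  expect_gt(length(unique(best)), 1)

  # all betas zero, unit noise: values ~ N(0,1), per-dataset mean ~ 0
  m2 <- planted_performance_model(5, 3, main_sd = 0, interaction_sd = 0,
                                  noise_sd = 1, seed = 3)
  t2 <- generate_performance_table(m2, X, Z)
  per_mean <- tapply(t2$planted, t2$dataset_id, mean)
  expect_lt(max(abs(per_mean)), 4 / sqrt(12))
  expect_lt(abs(sd(t2$planted) - 1), 0.2)
})
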