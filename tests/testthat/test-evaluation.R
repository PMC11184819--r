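test_that("per-dataset correlations match the Pearson formula", {
  obs <- c(1, 2, 3, 5)
  pred <- c(2, 1, 4, 6)
  r_hand <- sum((pred - mean(pred)) * (obs - mean(obs))) /
    sqrt(sum((pred - mean(pred))^2) * sum((obs - mean(obs))^2))
  out <- per_dataset_correlation(pred, obs, rep("D1", 4))
  expect_equal(out$r, r_hand, tolerance = 1e-12)

  two <- per_dataset_correlation(c(obs, -obs), c(obs, obs),
                                 rep(c("A", "B"), each = 4))
  expect_equal(two$r, c(1, -1))
  # constant predictions have undefined correlation
  out_c <- per_dataset_correlation(rep(1, 4), obs, rep("D1", 4))
  expect_true(is.na(out_c$r))
})

test_that("signed-rank test against zero has the exact small-sample null", {
  expect_equal(wilcoxon_vs_zero(seq(0.1, 1, by = 0.1)), 2^-10,
               tolerance = 1e-12)
  p_sym <- wilcoxon_vs_zero(c(-4, -3, -2, -1, 1, 2, 3, 4) / 10)
  expect_gt(p_sym, 0.4); expect_lt(p_sym, 0.65)
  expect_equal(wilcoxon_vs_zero(rep(0, 6)), 1)
  expect_error(wilcoxon_vs_zero(c(0.1, 0.2)), "at least 5")

  # enumeration oracle at n = 8: brute-force over all sign assignments
  x <- c(0.11, 0.23, 0.05, 0.42, 0.31, 0.17, 0.08, 0.29)
  ranks <- rank(abs(x))
  v_obs <- sum(ranks[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
  v_null <- signs %*% ranks
  expect_equal(wilcoxon_vs_zero(x), mean(v_null >= v_obs), tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  p <- c(0.001, 0.01, 0.02, 0.8)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_true(all(adj <= 1))
})

test_that("ARI agreement correlates predictions with label overlap", {
  d <- separable_dataset(n_cells = 100, n_genes = 200, k = 3, seed = 91)
  grid <- enumerate_grid("default", "lognorm", 5,
                         c(0.1, 0.5, 1.0, 2.0))
  res <- run_grid(list(D1 = d), grid, seed = 42)
  aris <- vapply(res, function(r)
    adjusted_rand_index(r$labels, d$true_labels[names(r$labels)]),
    numeric(1))
  out <- ari_agreement(unname(aris), rep("D1", 4), grid$pipeline_id, res,
                       list(D1 = d$true_labels))
  expect_equal(nrow(out), 1)
  if (!is.na(out$r)) expect_equal(out$r, 1, tolerance = 1e-10)
  # restricted to datasets holding reference labels
  out2 <- ari_agreement(unname(aris), rep("D1", 4), grid$pipeline_id, res,
                        list())
  expect_null(out2)
})

test_that("determinant analysis is exact on perfect association and calibrated under the null", {
  feats <- data.frame(dataset_id = sprintf("D%02d", 1:12),
                      f1 = seq(-1, 1, length.out = 12),
                      f2 = rep(1, 12))
  perf <- data.frame(dataset_id = feats$dataset_id, r = feats$f1, n = 10)
  rep1 <- determinant_analysis(perf, feats)
  expect_equal(rep1$r[rep1$feature == "f1"], 1, tolerance = 1e-10)
  expect_lt(rep1$p[rep1$feature == "f1"], 1e-10)
  expect_false("f2" %in% rep1$feature)          # constant feature skipped
  expect_match(attr(rep1, "note"), "f2")

  # null calibration: p-values uniform over replicates
  pvals <- vapply(1:200, function(i) withr::with_seed(i, {
    f <- data.frame(dataset_id = sprintf("D%02d", 1:25), f1 = rnorm(25))
    pr <- data.frame(dataset_id = f$dataset_id, r = rnorm(25), n = 10)
    determinant_analysis(pr, f)$p
  }), numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)

  # t-based p agrees with a permutation p within Monte-Carlo error
  withr::with_seed(7, {
    f <- data.frame(dataset_id = sprintf("D%02d", 1:20), f1 = rnorm(20))
    pr <- data.frame(dataset_id = f$dataset_id,
                     r = 0.5 * f$f1 + rnorm(20), n = 10)
  })
  t_p <- determinant_analysis(pr, f)$p
  r_obs <- cor(f$f1, pr$r)
  perm_p <- withr::with_seed(8, mean(vapply(1:2000, function(i)
    abs(cor(sample(f$f1), pr$r)) >= abs(r_obs), numeric(1))))
  expect_lt(abs(t_p - perm_p), 0.05)
})

test_that("significant determinants are filtered across model blocks", {
  r1 <- data.frame(feature = c("a", "b"), r = c(0.9, 0.1),
                   p = c(0.001, 0.9))
  r2 <- data.frame(feature = c("a", "b"), r = c(0.5, 0.2),
                   p = c(0.2, 0.6))
  out <- significant_determinants(list(m1 = r1, m2 = r2))
  expect_setequal(unique(out$feature), "a")
  expect_equal(nrow(out), 2)
})
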