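# Independent brute-force oracles and fixture factories used across tests.
# The oracles evaluate the printed formulas directly with plain loops and
# never call the package implementations they check.

brute_ch <- function(X, labels) {
  X <- as.matrix(X)
  labs <- unique(labels)
  k <- length(labs); n <- nrow(X)
  mu <- colMeans(X)
  B <- 0; W <- 0
  for (l in labs) {
    Xc <- X[labels == l, , drop = FALSE]
    muc <- colMeans(Xc)
    B <- B + nrow(Xc) * sum((muc - mu)^2)
    for (i in seq_len(nrow(Xc))) W <- W + sum((Xc[i, ] - muc)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

brute_db <- function(X, labels) {
  X <- as.matrix(X)
  labs <- unique(labels)
  k <- length(labs)
  cent <- lapply(labs, function(l) colMeans(X[labels == l, , drop = FALSE]))
  s <- vapply(seq_len(k), function(ci) {
    Xc <- X[labels == labs[ci], , drop = FALSE]
    mean(vapply(seq_len(nrow(Xc)),
                function(i) sqrt(sum((Xc[i, ] - cent[[ci]])^2)), numeric(1)))
  }, numeric(1))
  r <- numeric(k)
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      d <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      best <- max(best, (s[i] + s[j]) / d)
    }
    r[i] <- best
  }
  mean(r)
}

brute_sil <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  labs <- unique(labels)
  d <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(labs, labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# random small clustered instance with every cluster non-empty
rand_instance <- function(n = 30, d = 3, k = 3, seed = 1) {
  withr::with_seed(seed, {
    labels <- c(seq_len(k), sample(seq_len(k), n - k, replace = TRUE))
    X <- matrix(rnorm(n * d), n, d) + 2 * labels
    list(X = X, labels = labels)
  })
}

# two (or more) Gaussian blobs with a given separation, as cell embeddings
make_blobs <- function(n_per = 50, k = 2, sep = 10, d = 5, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(k * d), k, d)
    centers <- centers / sqrt(rowSums(centers^2)) * sep
    X <- do.call(rbind, lapply(seq_len(k), function(c)
      sweep(matrix(rnorm(n_per * d), n_per, d), 2, centers[c, ], "+")))
    rownames(X) <- sprintf("C%04d", seq_len(k * n_per))
    list(emb = X, labels = rep(seq_len(k), each = n_per))
  })
}

# hand-constructable QC table with sensible defaults
make_qc <- function(n, log10_total_counts = rep(3, n),
                    log10_total_features = rep(2.5, n),
                    top20 = rep(30, n), featcount_dist = rep(0, n),
                    mito = rep(0.02, n)) {
  qc <- data.frame(
    cell_id = sprintf("C%04d", seq_len(n)),
    total_counts = 10^log10_total_counts,
    detected_features = round(10^log10_total_features),
    log10_total_counts = log10_total_counts,
    log10_total_features = log10_total_features,
    pct_counts_in_top_20_features = top20,
    pct_counts_in_top_50_features = pmin(top20 + 10, 100),
    pct_counts_in_top_100_features = pmin(top20 + 20, 100),
    pct_counts_in_top_200_features = pmin(top20 + 30, 100),
    pct_counts_Mt = mito,
    zero_total = rep(FALSE, n),
    featcount_dist = featcount_dist,
    stringsAsFactors = FALSE)
  class(qc) <- c("cell_qc", "data.frame")
  qc
}

# well-separated synthetic dataset for end-to-end clustering checks
separable_dataset <- function(n_cells = 250, n_genes = 600, k = 4, seed = 11) {
  generate_dataset(synth_config(
    n_cells = n_cells, n_genes = n_genes, n_clusters = k,
    de_prob = 0.3, logfc_sd = 2.5, nb_dispersion = 50,
    outlier_cell_frac = 0, seed = seed))
}
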