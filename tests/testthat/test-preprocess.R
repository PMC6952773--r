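test_that("TIC normalization equalizes totals and preserves proportions", {
  m <- matrix(rep(c(1, 2, 3), 4), 3, 4)  # identical columns: fixed point
  expect_equal(tic_normalize(make_layer(m)), make_layer(m))

  set.seed(1)
  m <- matrix(stats::rexp(100 * 12, rate = 1e-3), 100, 12)
  layer <- make_layer(m)
  norm <- tic_normalize(layer)
  nm <- as.matrix(norm[-1])
  sums <- colSums(nm)
  expect_lt(diff(range(sums)) / mean(sums), 1e-9)
  # explicit scale-by-(mean total / column total) oracle
  oracle <- sweep(m, 2, mean(colSums(m)) / colSums(m), `*`)
  expect_equal(unname(nm), unname(oracle), tolerance = 1e-12)
  # within-sample ranks unchanged
  expect_equal(apply(nm, 2, rank), apply(m, 2, rank),
               ignore_attr = TRUE)

  bad <- make_layer(cbind(m[, 1], 0))
  expect_error(tic_normalize(bad), "s02")
})

test_that("singlet filtering retains exactly features with >= 2 unique peptides", {
  set.seed(2)
  n <- 4881
  layer <- make_layer(matrix(stats::runif(n * 4, 1, 10), n, 4))
  singlets <- sample(n, 994)
  layer$unique_peptides <- ifelse(seq_len(n) %in% singlets, 1L,
                                  sample(2:10, n, replace = TRUE))
  kept <- filter_singletons(layer)
  expect_equal(nrow(kept), 3887)
  expect_true(all(kept$unique_peptides >= 2))
  expect_setequal(kept$feature_id, layer$feature_id[-singlets])

  # boundary: count 2 retained, count 1 removed
  two <- make_layer(matrix(1:4, 2, 2))
  two$unique_peptides <- c(1L, 2L)
  expect_equal(filter_singletons(two)$feature_id, "f002")
  expect_error(filter_singletons(make_layer(matrix(1:4, 2, 2))),
               "unique_peptides")
})

test_that("differential flags require both the change and the p threshold", {
  set.seed(3)
  md <- make_metadata(n = 6)
  base <- matrix(2^(8 + stats::rnorm(3 * 12, sd = 0.05)), 3, 12)
  # feature 1: strong change; feature 2: tiny change with tiny noise
  base[1, 7:12] <- base[1, 7:12] * 1.6
  base[2, 7:12] <- base[2, 7:12] * 1.05
  layer <- make_layer(base, sample_ids = md$sample_id)
  res <- differential_test(layer, md)
  expect_true(res$significant[1])
  r2 <- res[2, ]
  expect_lt(r2$p_value, 0.05)           # significant p ...
  expect_false(r2$significant)          # ... but change below 15%
  expect_true(all(res$ratio > 0))
  expect_error(differential_test(layer, md[c(1, 7), ]), "2 replicates")
})

test_that("differential p-values are uniform under the null", {
  cfg <- simulation_config(n_genes = 2000, effect_log2 = 0,
                           dev_effect_log2 = 0, seed = 11)
  ds <- simulate_multiomics(cfg)
  dt <- differential_test(tic_normalize(ds$layers$transcript),
                          ds$metadata, group = "fetal")
  ks <- suppressWarnings(stats::ks.test(dt$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
  # alpha-level calibration within 3 sigma of Binomial(2000, 0.05)
  frac <- mean(dt$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("PCA projection matches an SVD oracle and its invariants", {
  set.seed(4)
  # exact rank-2 matrix: two components explain everything
  u <- matrix(stats::rnorm(40), 20, 2)
  v <- matrix(stats::rnorm(12), 2, 6)
  layer <- make_layer(100 + u %*% v)
  pca <- pca_project(layer, n_components = 2)
  expect_equal(sum(pca$explained), 1, tolerance = 1e-10)

  m <- matrix(stats::rnorm(50 * 30), 50, 30)
  layer <- make_layer(m)
  pca <- pca_project(layer, n_components = 5)
  sc <- as.matrix(pca$scores[-1])
  gram <- crossprod(sc)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  # full-decomposition oracle for the variance fractions
  x <- t(m)
  x <- sweep(x, 2, colMeans(x))
  ev <- svd(x)$d^2
  expect_equal(pca$explained, (ev / sum(ev))[1:5], tolerance = 1e-8)
  # permutation invariance to sample order
  perm <- sample(30)
  pca2 <- pca_project(layer[c(1, 1 + perm)], n_components = 5)
  expect_equal(pca2$explained, pca$explained, tolerance = 1e-10)
  expect_lte(sum(pca$explained), 1)

  expect_error(pca_project(make_layer(matrix(3, 4, 4))), "degenerate")
  expect_error(pca_project(layer, n_components = 40), "exceeds")
})

test_that("silhouette-guided K-means picks the planted k", {
  set.seed(5)
  blobs <- rbind(matrix(stats::rnorm(60, 0), ncol = 2),
                 matrix(stats::rnorm(60, 10), ncol = 2))
  fit <- kmeans_silhouette(blobs, 2:6, seed = 5)
  expect_equal(fit$k, 2)

  # exact duplicated triplets of 3 distinct centers: k = 3, silhouette 1
  tri <- do.call(rbind, rep(list(matrix(c(0, 0, 5, 5, 10, 0),
                                        3, 2, byrow = TRUE)), 3))
  fit3 <- kmeans_silhouette(tri, 2:3, seed = 1)
  expect_equal(fit3$k, 3)
  expect_equal(fit3$silhouette$mean_silhouette[fit3$silhouette$k == 3], 1)

  # silhouette values agree with a direct pairwise-distance recomputation
  for (krow in seq_len(nrow(fit$silhouette))) {
    k <- fit$silhouette$k[krow]
    expect_equal(fit$silhouette$mean_silhouette[krow],
                 brute_silhouette(blobs, fit$fits[[as.character(k)]]$cluster),
                 tolerance = 1e-9)
  }
  expect_error(kmeans_silhouette(blobs, 2:200), "k_range")
  expect_error(kmeans_silhouette(tri, 2:4), "distinct")
})
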