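test_that("t-SNE embedding is seed-deterministic and caps the PCA dims", {
  fx <- make_profile_clusters(n_per = 30, seed = 2)
  e1 <- tsne_embed(fx$profiles, perplexity = 10, n_runs = 2,
                   base_seed = 42, max_iter = 300)
  e2 <- tsne_embed(fx$profiles, perplexity = 10, n_runs = 2,
                   base_seed = 42, max_iter = 300)
  expect_identical(e1$coords, e2$coords)
  # 20 input dimensions with n_pca = 50: all 20 used, no error
  expect_equal(e1$params$n_pca, 20)
  expect_error(tsne_embed(fx$profiles, perplexity = 40),
               "perplexity")
})

test_that("planted profile clusters are recovered with high ARI in nearly all runs", {
  fx <- make_profile_clusters(n_per = 40, seed = 3)
  emb <- tsne_embed(fx$profiles, perplexity = 10, n_runs = 15,
                    base_seed = 7, max_iter = 500, min_cluster = 5)
  aris <- apply(emb$labels, 2, function(lab) {
    mclust::adjustedRandIndex(lab, fx$truth)
  })
  expect_gte(sum(aris >= 0.9), 14)
  # stability agrees with the mean pairwise ARI recomputed by formula
  prs <- utils::combn(15, 2)
  oracle <- mean(vapply(seq_len(ncol(prs)), function(i) {
    ari_formula(emb$labels[, prs[1, i]], emb$labels[, prs[2, i]])
  }, numeric(1)))
  expect_equal(emb$stability, oracle, tolerance = 1e-12)
})

test_that("outlier-cluster extraction labels planted modules by direction", {
  fx <- make_profile_clusters(n_per = c(60, 25, 25), seed = 4)
  emb <- tsne_embed(fx$profiles, perplexity = 10, n_runs = 5,
                    base_seed = 11, max_iter = 500)
  ids <- fx$profiles$feature_id
  # clusters 2 and 3 are the planted outliers; direct them oppositely
  direction <- tibble::tibble(
    feature_id = ids,
    direction = c(0.1, 1, -1)[fx$truth] + 0
  )
  cl <- extract_outlier_clusters(emb, direction)
  lab <- cl$assignment$label
  expect_setequal(lab[fx$truth == 2], "group1")
  expect_setequal(lab[fx$truth == 3], "group2")
  expect_setequal(lab[fx$truth == 1], "background")

  # consensus equals a direct majority vote over aligned per-run labels
  vote <- apply(cl$aligned_labels, 1, function(v) {
    tab <- table(v)
    as.integer(names(tab)[order(-tab, as.integer(names(tab)))][1])
  })
  expect_equal(cl$assignment$consensus, unname(vote))
})

test_that("a single homogeneous cloud yields no outlier clusters", {
  set.seed(5)
  cloud <- make_layer(matrix(stats::rnorm(80 * 10), 80, 10))
  emb <- tsne_embed(cloud, perplexity = 10, n_runs = 3, base_seed = 3,
                    max_iter = 300)
  direction <- tibble::tibble(feature_id = cloud$feature_id,
                              direction = stats::rnorm(80))
  cl <- suppressWarnings(extract_outlier_clusters(emb, direction))
  expect_true(all(cl$assignment$label == "background"))
})

test_that("hypergeometric enrichment matches exact mass summation", {
  universe <- paste0("g", 1:20)
  db <- tibble::tibble(term = "t1", description = "d",
                       members = list(paste0("g", 1:6)))
  query <- c(paste0("g", 1:5), paste0("g", 15:17))  # k=5, n=8, K=6, N=20
  res <- enrich(query, db, universe)
  oracle <- sum(stats::dhyper(5:6, 6, 14, 8))
  expect_equal(res$p_value, oracle, tolerance = 1e-12)
  expect_equal(res$count_in_set, "5/6")

  # disjoint query -> k = 0, p = 1; query = universe -> all k = K, p = 1
  res0 <- enrich(paste0("g", 10:14), db, universe)
  expect_equal(res0$k, 0)
  expect_equal(res0$p_value, 1)
  resU <- enrich(universe, db, universe)
  expect_equal(resU$k, resU$K)
  expect_equal(resU$p_value, 1)
  expect_error(enrich("g1", db, character(0)), "universe")
  expect_error(enrich("zz", db, universe), "outside")
})

test_that("enrichment is invariant to relabeling and monotone in hits", {
  set.seed(6)
  universe <- paste0("g", 1:30)
  db <- tibble::tibble(term = c("t1", "t2"), description = "d",
                       members = list(paste0("g", 1:8), paste0("g", 9:20)))
  query <- sample(universe, 10)
  res <- enrich(query, db, universe)
  # relabel every gene id consistently
  relab <- stats::setNames(paste0("x", 1:30), universe)
  db2 <- db
  db2$members <- lapply(db$members, function(m) unname(relab[m]))
  res2 <- enrich(unname(relab[query]), db2, paste0("x", 1:30))
  expect_equal(res$p_value, res2$p_value)

  # adding a hit never increases that term's p (exhaustive small check)
  for (k in 0:5) {
    q1 <- c(head(universe, k), paste0("g", 21:25))
    q2 <- c(head(universe, k + 1), paste0("g", 21:25))
    p1 <- enrich(q1, db[1, ], universe)$p_value
    p2 <- enrich(q2, db[1, ], universe)$p_value
    expect_lte(p2, p1)
  }
})
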