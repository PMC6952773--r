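test_that("layer mapping equals an exhaustive join oracle", {
  layers <- list(
    transcript = make_layer(matrix(1, 3, 2), c("g1", "g2", "g3")),
    protein = make_layer(matrix(1, 3, 2), c("g1", "g2", "g4")),
    metabolite = make_layer(matrix(1, 2, 2), c("m1", "m2"))
  )
  pdb <- tibble::tibble(
    term = c("pwA", "pwB"),
    description = c("a", "b"),
    members = list(c("g1", "g2", "m1"), c("g3", "m2"))
  )
  gcm <- tibble::tibble(gene = c("g1", "g2", "g3", "g4"),
                        cluster = c("c1", "c1", "c2", "c3"))
  res <- map_layers(layers, pdb, gcm)
  mem <- res$membership

  # metabolite in exactly one pathway -> one membership row
  expect_equal(sum(mem$entity == "metabolite:m1"), 1)
  # g4 is in no pathway (cluster c3 untouched) -> unmapped only
  expect_false("protein:g4" %in% mem$entity)
  expect_true(any(res$unmapped$feature_id == "g4" &
                    res$unmapped$layer == "protein"))
  # transcripts map through clusters: g1,g2 share c1, both in pwA
  expect_setequal(mem$pathway[mem$entity == "transcript:g1"], "pwA")

  # exhaustive set-join oracle over every (layer, feature, pathway)
  cluster_of <- stats::setNames(gcm$cluster, gcm$gene)
  oracle <- list()
  for (tag in names(layers)) {
    for (ft in layers[[tag]]$feature_id) {
      for (i in seq_len(nrow(pdb))) {
        members <- pdb$members[[i]]
        hit <- if (tag == "transcript") {
          cl <- cluster_of[ft]
          !is.na(cl) &&
            any(stats::na.omit(cluster_of[members]) == cl)
        } else {
          ft %in% members
        }
        if (hit) {
          oracle[[length(oracle) + 1]] <-
            paste(tag, ft, pdb$term[i], sep = "|")
        }
      }
    }
  }
  got <- paste(mem$layer, mem$feature_id, mem$pathway, sep = "|")
  expect_setequal(got, unlist(oracle))
})

test_that("Fisher combination matches its closed forms and monotonicity", {
  expect_equal(fisher_combine(c(1, 1))$statistic, 0)
  expect_equal(fisher_combine(c(1, 1))$p_value, 1)
  # single p: chi-square survival at 2 df inverts exactly
  expect_equal(fisher_combine(0.05)$p_value, 0.05, tolerance = 1e-14)

  fc <- fisher_combine(c(0.01, 0.02, 0.03))
  x2 <- -2 * sum(log(c(0.01, 0.02, 0.03)))
  # independent chi-square tail oracle: closed-form survival at even df
  surv_even_df <- function(x, k) {
    exp(-x / 2) * sum((x / 2)^(0:(k - 1)) / factorial(0:(k - 1)))
  }
  expect_equal(fc$p_value, surv_even_df(x2, 3), tolerance = 1e-12)

  # permutation invariance and monotonicity
  set.seed(6)
  p <- stats::runif(4)
  expect_equal(fisher_combine(p)$p_value,
               fisher_combine(rev(p))$p_value)
  p2 <- p; p2[2] <- p2[2] / 2
  expect_lte(fisher_combine(p2)$p_value, fisher_combine(p)$p_value)
  expect_error(fisher_combine(c(0.5, 0)), "p-values")
  expect_error(fisher_combine(c(0.5, 1.2)), "p-values")
  expect_error(fisher_combine(numeric(0)), "no p-values")
})

test_that("pathway p-value matches exhaustive enumeration on a small instance", {
  set.seed(7)
  stats_tbl <- tibble::tibble(feature_id = paste0("f", 1:10),
                              z = stats::rnorm(10, sd = 2))
  members <- c("f2", "f5", "f9")
  p <- pathway_pvalue(stats_tbl, members, exact = TRUE)
  absz <- abs(stats_tbl$z)
  obs <- mean(absz[c(2, 5, 9)])
  sets <- utils::combn(10, 3)
  oracle <- mean(colMeans(matrix(absz[sets], nrow = 3)) >= obs - 1e-12)
  expect_equal(p, oracle)

  # a pathway holding exactly the top-ranked features floors the
  # permutation p (universe large enough that redrawing the same set is
  # negligible)
  set.seed(10)
  big <- tibble::tibble(feature_id = paste0("f", 1:300),
                        z = stats::rnorm(300))
  top <- big$feature_id[order(-abs(big$z))][1:10]
  pf <- pathway_pvalue(big, top, n_perm = 999, seed = 1)
  expect_equal(pf, 1 / 1000)

  expect_true(is.na(pathway_pvalue(stats_tbl, c("f1", "f2"))))
})

test_that("null pathway p-values are uniform", {
  set.seed(8)
  stats_tbl <- tibble::tibble(feature_id = paste0("f", 1:300),
                              z = stats::rnorm(300))
  ps <- vapply(1:400, function(i) {
    pathway_pvalue(stats_tbl, sample(stats_tbl$feature_id, 10),
                   n_perm = 299)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("capped assignment: elementary retain/drop behavior", {
  mem <- tibble::tibble(
    entity = c("e1", "e2", "e3", "e4", "e5", "e6"),
    pathway = rep(c("pwA", "pwB"), each = 3)
  )
  sc <- tibble::tibble(pathway = c("pwA", "pwB"), score = c(5, 3))
  # disjoint members: everything retained regardless of cap
  sol <- dp_rank(sc, mem, cap = 1, min_members = 3)
  expect_setequal(sol$retained, c("pwA", "pwB"))
  expect_equal(sol$objective, 8)
  expect_equal(sol$regime, "exact")

  # identical members, cap 1: only the higher-scoring pathway survives
  mem2 <- tibble::tibble(entity = rep(c("e1", "e2", "e3"), 2),
                         pathway = rep(c("pwA", "pwB"), each = 3))
  sol2 <- dp_rank(sc, mem2, cap = 1, min_members = 3)
  expect_equal(sol2$retained, "pwA")
  expect_equal(sol2$objective, 5)
  # with cap 2 both can keep the shared entities
  sol3 <- dp_rank(sc, mem2, cap = 2, min_members = 3)
  expect_setequal(sol3$retained, c("pwA", "pwB"))
  expect_error(dp_rank(sc, mem2, cap = 0), "cap")
})

test_that("assignment solutions respect the cap and retention invariants", {
  set.seed(9)
  for (i in 1:20) {
    np <- sample(3:6, 1); ne <- sample(5:10, 1); cap <- sample(1:2, 1)
    pws <- paste0("pw", seq_len(np))
    mem <- tibble::tibble(
      entity = sample(paste0("e", seq_len(ne)), ne * 2, replace = TRUE),
      pathway = sample(pws, ne * 2, replace = TRUE)
    )
    mem <- unique(mem)
    sc <- tibble::tibble(pathway = pws, score = stats::runif(np, 0.5, 5))
    sol <- dp_rank(sc, mem, cap = cap, min_members = 2)
    counts <- table(sol$assignments$entity)
    if (length(counts) > 0) expect_lte(max(counts), cap)
    kept <- table(sol$assignments$pathway)
    if (length(sol$retained) > 0) {
      expect_true(all(kept[sol$retained] >= 2))
    }
    # assignments only along membership edges
    expect_true(all(paste(sol$assignments$entity, sol$assignments$pathway)
                    %in% paste(mem$entity, mem$pathway)))
    # greedy lower bounds: exact >= greedy >= best single pathway
    greedy <- triomix:::dp_greedy(pws, stats::setNames(sc$score, pws),
                                  mem, cap, 2)
    expect_gte(sol$objective + 1e-9, sum(sc$score[sc$pathway %in%
                                                    greedy$retained]))
    singles <- vapply(pws, function(pw) {
      sum(mem$pathway == pw) >= 2
    }, logical(1))
    if (any(singles)) {
      expect_gte(sum(sc$score[sc$pathway %in% greedy$retained]) + 1e-9,
                 max(sc$score[singles]))
    }
  }
})

test_that("ranked report applies BH and the documented tie-breaks", {
  scores <- tibble::tibble(
    pathway = c("pwC", "pwA", "pwB"),
    p_combined = c(0.001, 0.5, 0.001),
    score = -log10(c(0.001, 0.5, 0.001))
  )
  mem <- tibble::tibble(
    entity = c(paste0("e", 1:6), paste0("e", 1:3)),
    pathway = c(rep("pwC", 6), rep("pwB", 3))
  )
  sol <- dp_rank(scores, mem, cap = 2, min_members = 3)
  rep <- rank_report(sol, scores)
  # tie on p broken by retained entities (pwC keeps 6, pwB keeps 3)
  expect_equal(rep$pathway[1:2], c("pwC", "pwB"))
  # BH oracle: direct step-up recomputation
  o <- order(scores$p_combined)
  n <- 3
  bh <- scores$p_combined[o] * n / seq_len(n)
  bh <- rev(cummin(rev(bh)))
  expect_equal(rep$fdr[match(scores$pathway[o], rep$pathway)],
               pmin(bh, 1))
  # single pathway: FDR equals its p
  one <- scores[1, ]
  sol1 <- dp_rank(one, mem[mem$pathway == "pwC", ], cap = 1)
  rep1 <- rank_report(sol1, one)
  expect_equal(rep1$fdr, rep1$p_combined)
  # all p = 1 -> all FDR = 1
  allone <- tibble::tibble(pathway = c("x", "y"), p_combined = c(1, 1),
                           score = c(0, 0))
  rep2 <- rank_report(dp_rank(allone, mem[0, ], cap = 1), allone)
  expect_true(all(rep2$fdr == 1))
})
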