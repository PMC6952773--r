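#' Seeded t-SNE embedding, repeated for stability
#'
#' Embeds feature profiles in 2-D with Barnes-Hut t-SNE, preceded by a
#' PCA reduction, and repeats the embedding `n_runs` times with seeds
#' `base_seed + 1 .. base_seed + n_runs` to assess the stability of the
#' clustering pattern. Each run is density-clustered (see
#' [density_labels()]) and the stability score is the mean pairwise
#' adjusted Rand index of those labels across runs.
#'
#' @param profiles tibble: `feature_id` plus numeric profile columns.
#' @param perplexity t-SNE perplexity (default 20).
#' @param n_pca number of PCA components used before embedding (default
#'   50; capped at the available dimensionality).
#' @param exaggeration early-exaggeration factor (default 4).
#' @param n_runs number of seeded repeats (default 15).
#' @param base_seed base RNG seed.
#' @param max_iter t-SNE iterations (default 1000).
#' @param theta Barnes-Hut accuracy trade-off (default 0.5).
#' @param eps_quantile,knn,min_cluster density-labeling parameters, see
#'   [density_labels()].
#' @return object of class `triomix_embedding`: list with `coords`
#'   (tibble `run`, `feature_id`, `x`, `y`), `labels` (matrix features x
#'   runs of per-run density labels, 0 = background/noise), `stability`,
#'   `params`.
#' @export
tsne_embed <- function(profiles, perplexity = 20, n_pca = 50,
                       exaggeration = 4, n_runs = 15, base_seed = 1,
                       max_iter = 1000, theta = 0.5,
                       eps_quantile = 0.9, knn = 5, min_cluster = 5) {
  m <- layer_matrix(profiles)
  if (any(!is.finite(m))) abort("profiles must be finite")
  n <- nrow(m)
  if (perplexity >= (n - 1) / 3) {
    abort("perplexity too large: need n_features > 3 * perplexity + 1")
  }
  dims <- min(n_pca, ncol(m), n - 1)
  coords <- vector("list", n_runs)
  labels <- matrix(0L, nrow = n, ncol = n_runs,
                   dimnames = list(profiles$feature_id, NULL))
  for (r in seq_len(n_runs)) {
    set.seed(base_seed + r)
    fit <- Rtsne::Rtsne(m, dims = 2, perplexity = perplexity,
                        initial_dims = dims, pca = TRUE,
                        exaggeration_factor = exaggeration,
                        max_iter = max_iter, theta = theta,
                        check_duplicates = FALSE, verbose = FALSE)
    coords[[r]] <- tibble(run = r, feature_id = profiles$feature_id,
                          x = fit$Y[, 1], y = fit$Y[, 2])
    labels[, r] <- density_labels(fit$Y, eps_quantile = eps_quantile,
                                  knn = knn, min_cluster = min_cluster)
  }
  stability <- if (n_runs > 1) {
    prs <- combn(n_runs, 2)
    mean(vapply(seq_len(ncol(prs)), function(i) {
      mclust::adjustedRandIndex(labels[, prs[1, i]], labels[, prs[2, i]])
    }, numeric(1)))
  } else {
    NA_real_
  }
  structure(
    list(coords = dplyr::bind_rows(coords), labels = labels,
         stability = stability,
         params = list(perplexity = perplexity, n_pca = dims,
                       exaggeration = exaggeration, n_runs = n_runs,
                       base_seed = base_seed, max_iter = max_iter,
                       theta = theta, eps_quantile = eps_quantile,
                       knn = knn, min_cluster = min_cluster)),
    class = "triomix_embedding"
  )
}

#' Density-based labels on a 2-D embedding
#'
#' Connects points closer than a neighborhood radius eps — the
#' `eps_quantile` quantile of the `knn`-th nearest-neighbor distances —
#' and labels the connected components. Components smaller than
#' `min_cluster` are noise (label 0). Labels are renumbered by
#' decreasing component size (1 = largest).
#'
#' @param coords numeric matrix (n x 2) of embedding coordinates.
#' @param eps_quantile quantile of k-NN distances for the radius.
#' @param knn which nearest neighbor distance to use (default 5).
#' @param min_cluster minimum component size (default 5).
#' @return integer vector of labels (0 = noise).
#' @export
density_labels <- function(coords, eps_quantile = 0.9, knn = 5,
                           min_cluster = 5) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  knn_d <- apply(d, 1, function(r) sort(r)[knn + 1])  # skip self
  eps <- quantile(knn_d, eps_quantile, names = FALSE)
  # connected components of the eps-graph via union-find
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  adj <- which(d <= eps & upper.tri(d), arr.ind = TRUE)
  for (k in seq_len(nrow(adj))) {
    a <- find(adj[k, 1]); b <- find(adj[k, 2])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n), find, integer(1))
  sizes <- table(comp)
  big <- names(sizes)[sizes >= min_cluster]
  ord <- big[order(-sizes[big], as.integer(big))]
  labels <- integer(n)
  for (i in seq_along(ord)) labels[comp == as.integer(ord[i])] <- i
  labels
}

#' Extract outlier clusters from a repeated embedding
#'
#' Aligns the per-run density labels to the first run (greedy maximal
#' overlap), takes the majority label per feature as the consensus, and
#' calls every consensus cluster other than the largest one (the main
#' data stream) an outlier cluster. Outlier clusters are labeled by the
#' sign of their members' mean fetal-minus-adult profile: positive →
#' `group1` (up in fetal), negative → `group2` (down in fetal);
#' everything else is `background`.
#'
#' @param embedding a `triomix_embedding`.
#' @param direction tibble `feature_id`, `direction` (mean fetal minus
#'   adult log2 intensity per feature).
#' @param stability_min warn when the embedding stability is below this
#'   (default 0.8).
#' @param min_cluster minimum consensus cluster size (default taken from
#'   the embedding parameters).
#' @return object of class `triomix_clusters`: list with `assignment`
#'   (tibble `feature_id`, `consensus`, `label`), `stability`, `status`
#'   (`"ok"`, `"unstable"`, or `"no_clusters"`), `aligned_labels`.
#' @export
extract_outlier_clusters <- function(embedding, direction,
                                     stability_min = 0.8,
                                     min_cluster = NULL) {
  labels <- embedding$labels
  if (is.null(min_cluster)) min_cluster <- embedding$params$min_cluster
  status <- "ok"
  if (!is.na(embedding$stability) &&
      embedding$stability < stability_min) {
    status <- "unstable"
    warn(sprintf("embedding stability %.2f below %.2f",
                 embedding$stability, stability_min))
  }
  if (all(labels <= 1)) {
    return(structure(
      list(assignment = tibble(feature_id = rownames(labels),
                               consensus = 0L,
                               label = "background"),
           stability = embedding$stability, status = "no_clusters",
           aligned_labels = labels),
      class = "triomix_clusters"))
  }
  aligned <- align_run_labels(labels)
  consensus <- apply(aligned, 1, majority_label)
  sizes <- table(consensus[consensus > 0])
  main <- if (length(sizes) > 0) {
    as.integer(names(sizes)[which.max(sizes)])
  } else {
    0L
  }
  dir <- setNames(direction$direction, direction$feature_id)
  lab <- rep("background", nrow(aligned))
  for (cl in as.integer(names(sizes))) {
    if (cl == main || sizes[as.character(cl)] < min_cluster) next
    mean_dir <- mean(dir[rownames(aligned)[consensus == cl]], na.rm = TRUE)
    lab[consensus == cl] <- if (isTRUE(mean_dir >= 0)) "group1" else "group2"
  }
  structure(
    list(assignment = tibble(feature_id = rownames(aligned),
                             consensus = as.integer(consensus),
                             label = lab),
         stability = embedding$stability, status = status,
         aligned_labels = aligned),
    class = "triomix_clusters"
  )
}

# Align cluster labels of every run to run 1 by greedy maximal overlap of
# the contingency table; unmatched labels get fresh ids.
align_run_labels <- function(labels) {
  ref <- labels[, 1]
  out <- labels
  next_id <- max(labels) + 1L
  for (r in seq_len(ncol(labels))[-1]) {
    cur <- labels[, r]
    mapping <- c("0" = 0L)
    cls <- setdiff(unique(cur), 0L)
    refs <- setdiff(unique(ref), 0L)
    if (length(cls) > 0 && length(refs) > 0) {
      ov <- outer(cls, refs,
                  Vectorize(function(a, b) sum(cur == a & ref == b)))
      while (any(ov > 0)) {
        ij <- which(ov == max(ov), arr.ind = TRUE)[1, ]
        mapping[as.character(cls[ij[1]])] <- refs[ij[2]]
        ov[ij[1], ] <- -1L
        ov[, ij[2]] <- -1L
      }
    }
    unmatched <- setdiff(as.character(cls), names(mapping))
    for (cl in unmatched) {
      mapping[cl] <- next_id
      next_id <- next_id + 1L
    }
    out[, r] <- unname(mapping[as.character(cur)])
  }
  out
}

# Majority vote over one feature's aligned run labels; ties break to the
# smallest label so background (0) wins drawn votes.
majority_label <- function(v) {
  tab <- table(v)
  as.integer(names(tab)[order(-tab, as.integer(names(tab)))][1])
}

#' @export
print.triomix_embedding <- function(x, ...) {
  cat("t-SNE embedding:", nrow(x$labels), "features,",
      x$params$n_runs, "runs, stability =",
      sprintf("%.3f", x$stability), "\n")
  invisible(x)
}

#' @rdname tsne_embed
#' @param x a `triomix_embedding`.
#' @param ... unused.
#' @export
tidy.triomix_embedding <- function(x, ...) x$coords

#' @rdname tsne_embed
#' @export
glance.triomix_embedding <- function(x, ...) {
  tibble(n_features = nrow(x$labels), n_runs = x$params$n_runs,
         stability = x$stability, perplexity = x$params$perplexity,
         exaggeration = x$params$exaggeration)
}

#' @export
print.triomix_clusters <- function(x, ...) {
  tab <- table(x$assignment$label)
  cat("Consensus clusters (status ", x$status, "): ",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname extract_outlier_clusters
#' @param x a `triomix_clusters`.
#' @param ... unused.
#' @export
tidy.triomix_clusters <- function(x, ...) x$assignment

#' Hypergeometric annotation enrichment
#'
#' One-sided overlap test of a query feature set against each annotation
#' term, with Benjamini-Hochberg control across the tested terms. Terms
#' are intersected with the universe first; terms smaller than
#' `min_term_size` after intersection are skipped.
#'
#' @param query character vector of query features (must lie in
#'   `universe`).
#' @param annotation_db tibble from [read_gmt()] (`term`, `description`,
#'   `members`).
#' @param universe character vector: the background feature set.
#' @param min_term_size smallest testable term (default 3).
#' @return tibble sorted by p: `term`, `description`, `k` (hits), `K`
#'   (term size), `count_in_set` (`"k/K"`), `p_value`, `fdr`.
#' @export
enrich <- function(query, annotation_db, universe, min_term_size = 3) {
  if (length(universe) == 0) abort("empty universe")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) {
    abort("query contains features outside the universe")
  }
  N <- length(universe)
  n <- length(query)
  rows <- pmap(annotation_db[c("term", "description", "members")],
               function(term, description, members) {
    mem <- intersect(unique(members), universe)
    K <- length(mem)
    if (K < min_term_size) return(NULL)
    k <- length(intersect(query, mem))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(term = term, description = description, k = k, K = K,
           count_in_set = paste0(k, "/", K), p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(term = character(), description = character(),
                  k = integer(), K = integer(), count_in_set = character(),
                  p_value = numeric(), fdr = numeric()))
  }
  out$fdr <- p.adjust(out$p_value, method = "BH")
  dplyr::arrange(out, .data$p_value, .data$term)
}
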