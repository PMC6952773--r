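#' Total-ion-count normalization
#'
#' Rescales each sample column so that all column totals equal the mean of
#' the original totals, the usual equal-TIC assumption for label-based
#' quantitative proteomics. Within-sample feature proportions are
#' unchanged.
#'
#' @param layer layer tibble (`feature_id` plus sample columns; extra
#'   annotation columns such as `unique_peptides` are passed through).
#' @return the layer with rescaled sample columns.
#' @export
tic_normalize <- function(layer) {
  check_unique_ids(layer)
  cols <- layer_sample_cols(layer)
  m <- as.matrix(layer[cols])
  if (any(m < 0)) abort("negative intensities are not supported")
  totals <- colSums(m)
  zero <- totals == 0
  if (any(zero)) {
    abort(paste0("zero total ion count in sample(s): ",
                 paste(cols[zero], collapse = ", ")))
  }
  target <- mean(totals)
  layer[cols] <- as_tibble(sweep(m, 2, target / totals, `*`))
  layer
}

#' Remove singlet protein entries
#'
#' Drops features identified by fewer than `min_peptides` unique peptides;
#' proteins resting on a single unique peptide are unreliable and are
#' removed before quantitative analysis.
#'
#' @param layer layer tibble carrying a `unique_peptides` column.
#' @param min_peptides minimum unique-peptide count to retain (default 2).
#' @return the filtered layer.
#' @export
filter_singletons <- function(layer, min_peptides = 2) {
  if (!"unique_peptides" %in% names(layer)) {
    abort("layer has no 'unique_peptides' column")
  }
  dplyr::filter(layer, .data$unique_peptides >= min_peptides)
}

# Vectorized Welch two-sample t-test on the rows of a (log-scale) matrix.
# Returns per-row t, df and two-sided p for columns `a` versus `b`.
welch_rows <- function(m, a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort("need at least 2 replicates per condition")
  }
  xa <- m[, a, drop = FALSE]
  xb <- m[, b, drop = FALSE]
  na <- length(a); nb <- length(b)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- row_vars(xa); vb <- row_vars(xb)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  bad <- !is.finite(tt)
  tt[bad] <- 0
  df[bad] <- na + nb - 2
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

#' Per-feature differential test between two conditions
#'
#' Welch's two-sample t-test on log2 intensities, with the fold-change
#' reported as a linear-scale ratio of condition means. A feature is
#' flagged significant when both `|ratio - 1| > min_change` and
#' `p < alpha` hold (the "change > 15%, p < 0.05" style of call).
#'
#' @param layer layer tibble.
#' @param metadata metadata tibble (`sample_id`, `group`, `condition`).
#' @param contrast length-2 character: numerator condition, denominator
#'   condition (default `c("hypoxia", "normoxia")`).
#' @param group restrict to one sample group (e.g. `"fetal"`); `NULL`
#'   pools all groups.
#' @param min_change minimum absolute linear change (default 0.15).
#' @param alpha significance level (default 0.05).
#' @return tibble: `feature_id`, `ratio`, `log2_fc`, `t`, `p_value`,
#'   `significant`.
#' @export
differential_test <- function(layer, metadata,
                              contrast = c("hypoxia", "normoxia"),
                              group = NULL, min_change = 0.15,
                              alpha = 0.05) {
  if (length(contrast) != 2) abort("contrast must name two conditions")
  md <- metadata
  if (!is.null(group)) md <- dplyr::filter(md, .data$group %in% !!group)
  a <- md$sample_id[md$condition == contrast[1]]
  b <- md$sample_id[md$condition == contrast[2]]
  if (length(a) < 2 || length(b) < 2) {
    abort("need at least 2 replicates per condition in the selected group")
  }
  m <- layer_matrix(layer, md[md$sample_id %in% c(a, b), ])
  lm2 <- safe_log2(m)
  w <- welch_rows(lm2, match(a, colnames(m)), match(b, colnames(m)))
  ratio <- rowMeans(m[, a, drop = FALSE]) / rowMeans(m[, b, drop = FALSE])
  tibble(
    feature_id = layer$feature_id,
    ratio = unname(ratio),
    log2_fc = unname(rowMeans(lm2[, a, drop = FALSE]) -
                       rowMeans(lm2[, b, drop = FALSE])),
    t = unname(w$t),
    p_value = unname(w$p),
    significant = unname(abs(ratio - 1) > min_change & w$p < alpha)
  )
}

#' Cross-group persistence statistic per feature
#'
#' For each sample group separately, computes the Welch-t z-score of the
#' condition contrast on log2 intensities, then combines the per-group
#' z-scores by Stouffer's method (sum / sqrt(k)). Features whose response
#' keeps one sign across every group — persistent effects — get large
#' |z|; group-specific or null features do not.
#'
#' @inheritParams differential_test
#' @return tibble: `feature_id`, `z` (combined), plus one `z_<group>`
#'   column per group.
#' @export
persistence_stats <- function(layer, metadata,
                              contrast = c("hypoxia", "normoxia")) {
  groups <- unique(metadata$group)
  m <- layer_matrix(layer, metadata)
  lm2 <- safe_log2(m)
  zs <- lapply(groups, function(g) {
    md <- metadata[metadata$group == g, ]
    a <- md$sample_id[md$condition == contrast[1]]
    b <- md$sample_id[md$condition == contrast[2]]
    w <- welch_rows(lm2, match(a, colnames(m)), match(b, colnames(m)))
    # signed z from the two-sided p keeps Welch's df correction
    sign(w$t) * qnorm(pmax(w$p / 2, 1e-300), lower.tail = FALSE)
  })
  zmat <- do.call(cbind, zs)
  out <- tibble(feature_id = layer$feature_id,
                z = unname(rowSums(zmat) / sqrt(length(groups))))
  for (i in seq_along(groups)) out[[paste0("z_", groups[i])]] <- zmat[, i]
  out
}

#' Principal-component projection of samples
#'
#' Projects samples onto the principal axes of the column-centered
#' feature matrix (samples are observations, features variables).
#'
#' @param layer layer tibble.
#' @param n_components number of components to keep.
#' @return object of class `triomix_pca`: list with `scores` (tibble:
#'   `sample_id`, `PC1..`), `explained` (variance fractions for the kept
#'   components), `rotation` (feature loadings).
#' @export
pca_project <- function(layer, n_components = 4) {
  m <- t(layer_matrix(layer))
  if (n_components > min(dim(m))) {
    abort("n_components exceeds min(features, samples)")
  }
  if (all(abs(sweep(m, 2, colMeans(m))) < 1e-12)) {
    abort("degenerate input: matrix is constant across samples")
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(sample_id = rownames(m)), scores)
  structure(
    list(scores = scores,
         explained = frac[seq_len(n_components)],
         rotation = pc$rotation[, seq_len(n_components), drop = FALSE]),
    class = "triomix_pca"
  )
}

#' @export
print.triomix_pca <- function(x, ...) {
  cat("PCA projection:", nrow(x$scores), "samples,",
      length(x$explained), "components;",
      sprintf("%.1f%% variance covered\n", 100 * sum(x$explained)))
  invisible(x)
}

#' Silhouette-guided K-means
#'
#' Runs K-means for each candidate number of clusters and picks the k
#' that maximizes the mean silhouette width (ties go to the smallest k).
#'
#' @param points data frame or matrix of observations (rows) to cluster;
#'   an optional `sample_id`/`feature_id` first column is used for names.
#' @param k_range candidate cluster counts (default `2:10`).
#' @param nstart random restarts per k (default 25).
#' @param seed RNG seed for the restarts.
#' @return list of class `triomix_kmeans`: `k` (chosen), `labels`
#'   (integer vector named by row), `silhouette` (tibble: `k`,
#'   `mean_silhouette`), `fits` (kmeans objects by k).
#' @export
kmeans_silhouette <- function(points, k_range = 2:10, nstart = 25,
                              seed = 1) {
  ids <- NULL
  if (is.data.frame(points)) {
    idcol <- intersect(names(points), c("sample_id", "feature_id"))
    if (length(idcol) > 0) {
      ids <- as.character(points[[idcol[1]]])
      points <- points[setdiff(names(points), idcol)]
    }
    points <- as.matrix(points)
  }
  n <- nrow(points)
  if (any(k_range < 2) || any(k_range > n - 1)) {
    abort("k_range must lie within [2, n_points - 1]")
  }
  if (nrow(unique(points)) < max(k_range)) {
    abort("fewer distinct points than the largest k requested")
  }
  d <- dist(points)
  sil <- numeric(length(k_range))
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    set.seed(seed + k_range[i])
    fits[[i]] <- kmeans(points, centers = k_range[i], nstart = nstart,
                        iter.max = 50)
    sw <- cluster::silhouette(fits[[i]]$cluster, d)
    sil[i] <- mean(sw[, "sil_width"])
  }
  best <- which(sil == max(sil))[1]  # ties -> smallest k (k_range sorted)
  labels <- fits[[best]]$cluster
  if (!is.null(ids)) names(labels) <- ids
  structure(
    list(k = k_range[best], labels = labels,
         silhouette = tibble(k = k_range, mean_silhouette = sil),
         fits = setNames(fits, k_range)),
    class = "triomix_kmeans"
  )
}

#' @export
print.triomix_kmeans <- function(x, ...) {
  cat("K-means with silhouette-selected k =", x$k, "\n")
  print(x$silhouette)
  invisible(x)
}
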