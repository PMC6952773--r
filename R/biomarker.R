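#' MANOVA test of a feature panel
#'
#' Wilks' lambda for a one-way multivariate analysis of variance of the
#' panel's (log2) intensities against the condition labels, with Rao's F
#' approximation (exact F for two groups). The within/total SSCP
#' matrices are guarded against near-singularity: collinear panels are
#' rejected naming the features.
#'
#' @param x numeric matrix or data frame, samples in rows, panel
#'   features in columns.
#' @param labels factor-like vector of condition labels (length
#'   `nrow(x)`).
#' @param rcond_min reciprocal-condition threshold below which the panel
#'   is declared singular (default 1e-10).
#' @return one-row tibble: `wilks`, `f`, `df1`, `df2`, `p_value`.
#' @export
manova_test <- function(x, labels, rcond_min = 1e-10) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.factor(labels)
  n <- nrow(x); p <- ncol(x); g <- nlevels(labels)
  if (g < 2) abort("need at least two condition groups")
  if (n <= p + g - 1) abort("too few samples for this panel size")
  grand <- colMeans(x)
  xc <- sweep(x, 2, grand)
  total <- crossprod(xc)
  within <- matrix(0, p, p)
  for (lv in levels(labels)) {
    xi <- x[labels == lv, , drop = FALSE]
    xic <- sweep(xi, 2, colMeans(xi))
    within <- within + crossprod(xic)
  }
  if (rcond(total) < rcond_min || rcond(within) < rcond_min) {
    abort(paste0("singular panel (collinear features): ",
                 paste(colnames(x), collapse = ", ")))
  }
  lambda <- det(within) / det(total)
  q <- g - 1                       # hypothesis degrees of freedom
  s <- if (p^2 + q^2 - 5 > 0) {
    sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5))
  } else {
    1
  }
  m <- n - 1 - (p + q + 1) / 2
  df1 <- p * q
  df2 <- m * s - p * q / 2 + 1
  ls <- lambda^(1 / s)
  f <- (1 - ls) / ls * df2 / df1
  tibble(wilks = lambda, f = f, df1 = df1, df2 = df2,
         p_value = pf(f, df1, df2, lower.tail = FALSE))
}

#' Exhaustive MANOVA search over small feature panels
#'
#' Tests all combinations of 1 to `max_panel` features from a candidate
#' pool for their joint power to separate two conditions. The pool is
#' the `pool_size` features with the smallest univariate Welch-t
#' p-values (an exhaustive search over thousands of features is
#' infeasible; the restriction is recorded in the result). A panel is
#' flagged synergistic when its p-value beats the best singleton p-value
#' among its members.
#'
#' @param layer layer tibble.
#' @param metadata metadata tibble.
#' @param group restrict to one sample group (`NULL` pools all).
#' @param contrast length-2 character, numerator/denominator condition.
#' @param pool_size candidate pool size (default 20).
#' @param max_panel largest panel (default 6; panels too large for the
#'   sample size are skipped with a message).
#' @return object of class `panel_search`: list with `panels` (tibble:
#'   `panel` ("a+b+c"), `size`, `wilks`, `f`, `p_value`, `fdr`,
#'   `synergy`, sorted by p), `pool`, `group`, `skipped_sizes`.
#' @export
search_panels <- function(layer, metadata, group = NULL,
                          contrast = c("hypoxia", "normoxia"),
                          pool_size = 20, max_panel = 6) {
  if (pool_size < max_panel) abort("pool_size must be >= max_panel")
  md <- metadata
  if (!is.null(group)) md <- dplyr::filter(md, .data$group %in% !!group)
  keep <- md$condition %in% contrast
  md <- md[keep, ]
  if (min(table(md$condition)) < 2) {
    abort("need at least 2 replicates per condition")
  }
  uni <- differential_test(layer, md, contrast = contrast)
  pool <- head(dplyr::arrange(uni, .data$p_value, .data$feature_id),
               pool_size)$feature_id
  m <- t(safe_log2(layer_matrix(layer, md)))[md$sample_id, pool,
                                             drop = FALSE]
  labels <- md$condition
  n <- nrow(m)
  g <- length(unique(labels))
  feasible <- seq_len(max_panel)[seq_len(max_panel) < n - g + 1]
  skipped <- setdiff(seq_len(max_panel), feasible)
  if (length(skipped) > 0) {
    rlang::inform(paste0("panel sizes skipped (too few samples): ",
                         paste(skipped, collapse = ", ")))
  }
  single_p <- setNames(rep(NA_real_, length(pool)), pool)
  rows <- list()
  for (s in feasible) {
    combos <- combn(pool, s)
    for (j in seq_len(ncol(combos))) {
      feats <- combos[, j]
      res <- tryCatch(manova_test(m[, feats, drop = FALSE], labels),
                      error = function(e) NULL)
      if (is.null(res)) next
      if (s == 1) single_p[feats] <- res$p_value
      rows[[length(rows) + 1]] <- tibble(
        panel = paste(feats, collapse = "+"), size = s,
        wilks = res$wilks, f = res$f, p_value = res$p_value,
        best_single = min(single_p[feats], na.rm = TRUE)
      )
    }
  }
  panels <- dplyr::bind_rows(rows)
  panels$synergy <- panels$size > 1 & panels$p_value < panels$best_single
  panels$fdr <- p.adjust(panels$p_value, method = "BH")
  panels <- dplyr::arrange(panels, .data$p_value, .data$panel)
  structure(
    list(panels = panels, pool = pool, group = group,
         contrast = contrast, skipped_sizes = skipped),
    class = "panel_search"
  )
}

#' @export
print.panel_search <- function(x, ...) {
  cat("MANOVA panel search over a pool of", length(x$pool),
      "features:", nrow(x$panels), "panels tested\n")
  print(head(x$panels, 5))
  invisible(x)
}

#' @rdname search_panels
#' @param x a `panel_search`.
#' @param ... unused.
#' @export
tidy.panel_search <- function(x, ...) x$panels

#' @rdname search_panels
#' @export
glance.panel_search <- function(x, ...) {
  tibble(n_panels = nrow(x$panels), pool_size = length(x$pool),
         n_synergistic = sum(x$panels$synergy),
         best_p = min(x$panels$p_value))
}
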