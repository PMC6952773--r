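#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col labs
#'   theme_minimal coord_flip
#' @export
ggplot2::autoplot

#' @rdname pca_project
#' @param object a `triomix_pca`.
#' @param x_axis,y_axis which components to plot.
#' @param metadata optional metadata tibble for coloring by group and
#'   shaping by condition.
#' @param ... unused.
#' @export
autoplot.triomix_pca <- function(object, x_axis = "PC1", y_axis = "PC2",
                                 metadata = NULL, ...) {
  df <- object$scores
  p <- if (!is.null(metadata)) {
    df <- dplyr::left_join(df, metadata, by = "sample_id")
    ggplot(df, aes(.data[[x_axis]], .data[[y_axis]],
                   colour = .data$group, shape = .data$condition))
  } else {
    ggplot(df, aes(.data[[x_axis]], .data[[y_axis]]))
  }
  ix <- as.integer(sub("PC", "", c(x_axis, y_axis)))
  p + geom_point(size = 2) + theme_minimal() +
    labs(x = sprintf("%s (%.1f%%)", x_axis, 100 * object$explained[ix[1]]),
         y = sprintf("%s (%.1f%%)", y_axis, 100 * object$explained[ix[2]]))
}

#' @rdname pca_project
#' @export
tidy.triomix_pca <- function(x, ...) x$scores

#' @rdname pca_project
#' @param x a `triomix_pca`.
#' @export
glance.triomix_pca <- function(x, ...) {
  tibble(n_components = length(x$explained),
         variance_covered = sum(x$explained))
}

#' @rdname tsne_embed
#' @param object a `triomix_embedding`.
#' @param run which run to draw (default 1).
#' @export
autoplot.triomix_embedding <- function(object, run = 1, ...) {
  df <- object$coords[object$coords$run == run, ]
  df$cluster <- factor(object$labels[df$feature_id, run])
  ggplot(df, aes(.data$x, .data$y, colour = .data$cluster)) +
    geom_point(size = 1) + theme_minimal() +
    labs(title = sprintf("t-SNE run %d (stability %.2f)", run,
                         object$stability),
         x = "t-SNE 1", y = "t-SNE 2")
}

#' Plot an enrichment table
#'
#' Bar chart of `-log10(FDR)` for the top enriched terms.
#'
#' @param enrichment tibble from [enrich()].
#' @param top number of terms to show (default 15).
#' @return a ggplot.
#' @export
plot_enrichment <- function(enrichment, top = 15) {
  df <- head(enrichment, top)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot(df, aes(.data$term, -log10(.data$fdr))) +
    geom_col() + coord_flip() + theme_minimal() +
    labs(x = NULL, y = "-log10 FDR")
}

#' @rdname dp_rank
#' @param object an `assignment_solution`.
#' @export
autoplot.assignment_solution <- function(object, ...) {
  kept <- dplyr::count(object$assignments, .data$pathway,
                       name = "n_entities")
  kept$pathway <- factor(kept$pathway,
                         levels = kept$pathway[order(kept$n_entities)])
  ggplot(kept, aes(.data$pathway, .data$n_entities)) +
    geom_col() + coord_flip() + theme_minimal() +
    labs(y = "entities retained", x = NULL)
}

#' @rdname kmeans_silhouette
#' @param x a `triomix_kmeans`.
#' @param ... unused.
#' @export
tidy.triomix_kmeans <- function(x, ...) {
  tibble(id = if (!is.null(names(x$labels))) names(x$labels) else
           as.character(seq_along(x$labels)),
         cluster = unname(x$labels))
}

#' @rdname kmeans_silhouette
#' @export
glance.triomix_kmeans <- function(x, ...) {
  tibble(k = x$k,
         mean_silhouette =
           x$silhouette$mean_silhouette[x$silhouette$k == x$k])
}
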