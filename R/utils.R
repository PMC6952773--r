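#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_chr map_int map2 pmap imap keep
#' @importFrom stats pchisq pt phyper pf prcomp kmeans p.adjust qnorm sd
#'   var dist setNames quantile rnorm runif
#' @importFrom utils combn head
NULL

# Columns of a layer tibble that hold quantitative sample values.
# Reserved non-sample columns are feature_id and unique_peptides; if
# metadata is supplied, its sample_id column is authoritative.
layer_sample_cols <- function(layer, metadata = NULL) {
  stopifnot(is.data.frame(layer))
  if (!"feature_id" %in% names(layer)) {
    abort("layer must have a 'feature_id' column")
  }
  cand <- setdiff(names(layer), c("feature_id", "unique_peptides"))
  cand <- cand[vapply(layer[cand], is.numeric, logical(1))]
  if (!is.null(metadata)) {
    missing <- setdiff(metadata$sample_id, cand)
    if (length(missing) > 0) {
      abort(paste0("samples absent from layer: ",
                   paste(missing, collapse = ", ")))
    }
    cand <- intersect(cand, metadata$sample_id)
  }
  if (length(cand) == 0) abort("layer has no sample columns")
  cand
}

# Numeric matrix (features x samples) from a layer tibble.
layer_matrix <- function(layer, metadata = NULL) {
  cols <- layer_sample_cols(layer, metadata)
  m <- as.matrix(layer[cols])
  rownames(m) <- layer$feature_id
  m
}

check_unique_ids <- function(layer) {
  if (anyDuplicated(layer$feature_id)) {
    abort("duplicate feature ids in layer")
  }
  invisible(layer)
}

# Row-wise variance of a matrix without apply() overhead.
row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

# log2 with zeros replaced by half the smallest positive value in the
# matrix (the layer-wide pseudo-floor; see the methods vignette).
safe_log2 <- function(m) {
  if (any(m < 0)) abort("negative intensities are not supported")
  if (any(m == 0)) {
    pos <- m[m > 0]
    if (length(pos) == 0) abort("all intensities are zero")
    m[m == 0] <- min(pos) / 2
  }
  log2(m)
}
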