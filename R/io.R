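#' Read a quantitative omics matrix from TSV
#'
#' Features are rows; the first column (`feature_id`) holds feature
#' identifiers and the remaining columns are samples. Lines starting with
#' `#` are treated as comment headers and skipped. A `unique_peptides`
#' column, when present, is kept as an integer annotation rather than a
#' sample.
#'
#' @param path path to a tab-separated file.
#' @return a tibble with `feature_id` first.
#' @export
read_omics_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  if (ncol(x) < 2) abort(paste0("matrix file has no sample columns: ", path))
  names(x)[1] <- "feature_id"
  x$feature_id <- as.character(x$feature_id)
  check_unique_ids(x)
  x
}

#' Write a quantitative omics matrix to TSV
#'
#' @param layer layer tibble (`feature_id` plus sample columns).
#' @param path output path.
#' @param header optional character vector of comment lines (written with
#'   a leading `# `).
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(layer, path, header = NULL) {
  if (!is.null(header)) {
    writeLines(paste0("# ", header), path)
    readr::write_tsv(layer, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_tsv(layer, path, progress = FALSE)
  }
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line is `term <TAB> description <TAB> member1 <TAB> member2 ...`.
#' Lines with fewer than three fields, or with an empty member list after
#' dropping blank fields, are rejected with the offending line number.
#'
#' @param path path to a GMT file.
#' @return a tibble with columns `term`, `description` and a list-column
#'   `members`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    f <- f[f != ""]
    if (length(f) < 3) {
      abort(paste0("malformed GMT line ", i, " in ", path,
                   ": need term, description and >= 1 member"))
    }
    list(term = f[1], description = f[2], members = f[-(1:2)])
  })
  tibble(
    term = map_chr(rows, "term"),
    description = map_chr(rows, "description"),
    members = map(rows, "members")
  )
}

#' Write gene sets in GMT format
#'
#' @param sets tibble with `term`, `description`, `members` (list-column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- pmap(sets[c("term", "description", "members")],
                function(term, description, members) {
                  paste(c(term, description, members), collapse = "\t")
                })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read a two-column gene-to-cluster map
#'
#' A stand-in for sequence-similarity gene clusters: every mapped gene
#' belongs to exactly one cluster.
#'
#' @param path TSV with columns `gene`, `cluster` (header required).
#' @return tibble with `gene`, `cluster`.
#' @export
read_gene_clusters <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  if (!all(c("gene", "cluster") %in% names(x))) {
    abort(paste0("gene-cluster map must have columns gene, cluster: ", path))
  }
  if (anyDuplicated(x$gene)) {
    abort("gene-cluster map assigns some gene to more than one cluster")
  }
  x[c("gene", "cluster")]
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id`, `group`, `condition`.
#' @return metadata tibble.
#' @export
read_metadata <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  need <- c("sample_id", "group", "condition")
  if (!all(need %in% names(x))) {
    abort(paste0("metadata must have columns ",
                 paste(need, collapse = ", "), ": ", path))
  }
  x[need]
}

#' Read sequences from FASTA
#'
#' @param path FASTA file (wrapped sequence lines are concatenated).
#' @param type `"dna"` or `"aa"`.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- if (type == "dna") {
    Biostrings::readDNAStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  setNames(as.character(set), names(set))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
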