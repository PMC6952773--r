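# Small builders shared across test files. Everything is generated in
# code; no stored fixtures.

# A tiny layer tibble with the given matrix (features x samples).
make_layer <- function(m, feature_ids = NULL, sample_ids = NULL) {
  if (is.null(feature_ids)) {
    feature_ids <- sprintf("f%03d", seq_len(nrow(m)))
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(feature_ids, sample_ids)
  dplyr::bind_cols(tibble::tibble(feature_id = feature_ids),
                   tibble::as_tibble(m))
}

# Metadata for one group, two conditions, n replicates each.
make_metadata <- function(n = 5, group = "fetal") {
  tibble::tibble(
    sample_id = sprintf("%s_%s_%d", group,
                        rep(c("no", "hy"), each = n), rep(seq_len(n), 2)),
    group = group,
    condition = rep(c("normoxia", "hypoxia"), each = n)
  )
}

# Independent naive six-frame translation oracle: explicit codon loop
# over both strands using the standard genetic code.
naive_six_frame <- function(s, min_orf_len) {
  code <- Biostrings::GENETIC_CODE
  revcomp <- function(x) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  out <- list()
  L <- nchar(s)
  for (strand in c(1L, -1L)) {
    src <- if (strand == 1L) s else revcomp(s)
    for (f in 1:3) {
      aas <- character(0)
      pos <- f
      while (pos + 2 <= L) {
        cd <- substr(src, pos, pos + 2)
        aas <- c(aas, if (grepl("N", cd)) "X" else code[[cd]])
        pos <- pos + 3
      }
      if (length(aas) == 0) next
      runs <- rle(aas == "*")
      idx <- cumsum(c(1, runs$lengths))
      for (r in seq_along(runs$lengths)) {
        if (runs$values[r]) next
        a0 <- idx[r] - 1          # 0-based aa start within frame
        a1 <- a0 + runs$lengths[r]
        if (a1 - a0 < min_orf_len) next
        pep <- paste(aas[(a0 + 1):a1], collapse = "")
        s0 <- (f - 1) + 3 * a0
        s1 <- (f - 1) + 3 * a1
        if (strand == -1L) {
          tmp <- L - s1
          s1 <- L - s0
          s0 <- tmp
        }
        out[[length(out) + 1]] <- tibble::tibble(
          frame = strand * f, start = s0, end = s1, peptide = pep)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(frame = integer(), start = integer(),
                          end = integer(), peptide = character())
  }
  dplyr::arrange(res, frame, start)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_str <- function(x) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Brute-force mean-silhouette from pairwise distances (independent of
# cluster::silhouette).
brute_silhouette <- function(points, labels) {
  d <- as.matrix(dist(points))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- setdiff(own, i)
    if (length(own) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Adjusted Rand index from the contingency-table formula (independent of
# mclust).
ari_formula <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Brute-force optimum for the capped-assignment problem: enumerate all
# pathway subsets, checking feasibility with igraph max flow.
brute_force_objective <- function(scores, membership, cap, min_members) {
  pws <- scores$pathway
  sc <- stats::setNames(scores$score, pws)
  best <- 0
  for (mask in 0:(2^length(pws) - 1)) {
    keep <- pws[bitwAnd(mask, 2^(seq_along(pws) - 1)) > 0]
    if (sum(sc[keep]) <= best) next
    if (feasible_igraph(keep, membership, cap, min_members)) {
      best <- sum(sc[keep])
    }
  }
  best
}

feasible_igraph <- function(keep, membership, cap, min_members) {
  if (length(keep) == 0) return(TRUE)
  mem <- membership[membership$pathway %in% keep, ]
  mem <- unique(mem[c("entity", "pathway")])
  ents <- unique(mem$entity)
  if (length(ents) * cap < length(keep) * min_members) return(FALSE)
  nodes <- c("src", ents, keep, "snk")
  edges <- rbind(
    data.frame(from = "src", to = ents, cap = cap),
    data.frame(from = mem$entity, to = mem$pathway, cap = 1),
    data.frame(from = keep, to = "snk", cap = min_members)
  )
  g <- igraph::graph_from_data_frame(edges, vertices = nodes)
  f <- igraph::max_flow(g, source = "src", target = "snk",
                        capacity = edges$cap)
  f$value >= length(keep) * min_members
}

# Three well-separated profile clusters for embedding tests.
make_profile_clusters <- function(n_per = 40, dims = 20, sep = 12,
                                  seed = 1) {
  set.seed(seed)
  n_per <- rep_len(n_per, 3)
  centers <- rbind(rep(0, dims), c(rep(sep, dims / 2), rep(0, dims / 2)),
                   rep(-sep, dims))
  m <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(stats::rnorm(n_per[i] * dims), n_per[i], dims), 2,
          centers[i, ], `+`)
  }))
  list(profiles = make_layer(m), truth = rep(1:3, times = n_per))
}

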