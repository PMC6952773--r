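#' Map omics layers onto pathways and gene clusters
#'
#' Builds the long membership table used by pathway scoring: proteins and
#' transcripts belong to a pathway through their gene (transcripts via
#' their sequence-similarity gene cluster — a transcript is a member when
#' any gene of its cluster is in the pathway); metabolites belong when the
#' pathway lists them directly. Entities are `(layer, feature)` pairs so
#' the same gene measured in two layers counts as two data points.
#'
#' @param layers named list of layer tibbles; names are the layer tags
#'   (`transcript`, `protein`, `metabolite`).
#' @param pathway_db tibble from [read_gmt()]: `term`/`pathway`,
#'   `description`, `members` (gene and metabolite ids mixed).
#' @param gene_cluster_map tibble `gene`, `cluster` (used for the
#'   transcript layer; may be `NULL`, in which case transcripts map like
#'   proteins).
#' @return list: `membership` (tibble `entity`, `layer`, `feature_id`,
#'   `pathway`) and `unmapped` (tibble `layer`, `feature_id`).
#' @export
map_layers <- function(layers, pathway_db, gene_cluster_map = NULL) {
  if (nrow(pathway_db) == 0) abort("pathway_db is empty")
  pw_col <- if ("pathway" %in% names(pathway_db)) "pathway" else "term"
  pw <- tibble(pathway = pathway_db[[pw_col]],
               members = pathway_db$members)
  long <- tidyr::unnest(pw, "members")
  names(long)[names(long) == "members"] <- "member"

  cluster_of <- NULL
  if (!is.null(gene_cluster_map)) {
    cluster_of <- setNames(gene_cluster_map$cluster, gene_cluster_map$gene)
  }

  rows <- imap(layers, function(layer, tag) {
    feats <- layer$feature_id
    if (tag == "transcript" && !is.null(cluster_of)) {
      # pathway member genes -> clusters; transcript joins via its cluster
      member_cluster <- long
      member_cluster$cluster <- unname(cluster_of[member_cluster$member])
      member_cluster <- member_cluster[!is.na(member_cluster$cluster), ]
      feat_cluster <- tibble(feature_id = feats,
                             cluster = unname(cluster_of[feats]))
      feat_cluster <- feat_cluster[!is.na(feat_cluster$cluster), ]
      hits <- dplyr::inner_join(feat_cluster,
                                dplyr::distinct(member_cluster,
                                                .data$pathway, .data$cluster),
                                by = "cluster",
                                relationship = "many-to-many")
      hits <- dplyr::distinct(hits, .data$feature_id, .data$pathway)
    } else {
      hits <- dplyr::inner_join(tibble(feature_id = feats),
                                dplyr::distinct(long, member = .data$member,
                                                .data$pathway),
                                by = c(feature_id = "member"),
                                relationship = "many-to-many")
    }
    if (nrow(hits) == 0) {
      hits <- tibble(feature_id = character(), pathway = character())
    }
    tibble(entity = paste(tag, hits$feature_id, sep = ":"),
           layer = tag, feature_id = hits$feature_id,
           pathway = hits$pathway)
  })
  membership <- dplyr::bind_rows(rows)
  unmapped <- dplyr::bind_rows(imap(layers, function(lyr, tag) {
    mapped <- membership$feature_id[membership$layer == tag]
    um <- setdiff(lyr$feature_id, mapped)
    tibble(layer = rep(tag, length(um)), feature_id = um)
  }))
  list(membership = membership, unmapped = unmapped)
}

#' Competitive permutation p-value for one pathway in one layer
#'
#' Tests whether the pathway's member features are more perturbed than
#' random feature sets of the same size from the same layer: the observed
#' mean |z| of the members is compared with the permutation distribution
#' of mean |z| over random member sets, with the +1 continuity correction
#' `p = (1 + #{perm >= obs}) / (n_perm + 1)`, so p is floored at
#' `1/(n_perm + 1)`. With `exact = TRUE` all member sets of that size are
#' enumerated instead and `p = #{sets >= obs} / #sets` (the observed set
#' is one of them, so p > 0).
#'
#' @param stats tibble `feature_id`, `z` for all scored features of one
#'   layer (the competitive universe).
#' @param members character vector of member feature ids.
#' @param n_perm number of permutations (default 10000).
#' @param min_members minimum members with statistics (default 3); below
#'   it the pathway is not testable and `NA` is returned.
#' @param exact enumerate all member sets instead of sampling (only
#'   feasible for small instances).
#' @param seed RNG seed for the permutations.
#' @return scalar p-value (or `NA_real_` when not testable).
#' @export
pathway_pvalue <- function(stats, members, n_perm = 10000,
                           min_members = 3, exact = FALSE, seed = NULL) {
  absz <- abs(stats$z)
  idx <- match(unique(members), stats$feature_id)
  idx <- idx[!is.na(idx)]
  m <- length(idx)
  if (m < min_members) return(NA_real_)
  obs <- mean(absz[idx])
  n <- length(absz)
  if (exact) {
    if (choose(n, m) > 5e5) abort("exact enumeration infeasible at this size")
    sets <- combn(n, m)
    means <- colMeans(matrix(absz[sets], nrow = m))
    return(sum(means >= obs - 1e-12) / ncol(sets))
  }
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm),
                 function(i) mean(absz[sample.int(n, m)]), numeric(1))
  (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
}

#' Fisher's combined probability test
#'
#' Combines k independent p-values with the statistic
#' `X^2 = -2 * sum(log(p_i))`, referred to a chi-square distribution with
#' `2k` degrees of freedom.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return one-row tibble: `statistic` (X^2), `df`, `p_value`, `k`.
#' @export
fisher_combine <- function(p) {
  if (length(p) == 0) abort("no p-values to combine")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  x2 <- -2 * sum(log(p))
  k <- length(p)
  tibble(statistic = x2, df = 2 * k,
         p_value = pchisq(x2, df = 2 * k, lower.tail = FALSE), k = k)
}

#' Per-pathway Fisher combination across omics layers
#'
#' Computes the competitive permutation p-value of every pathway in every
#' layer (layers contributing fewer than `min_members` scored features to
#' a pathway are omitted for that pathway — the degrees of freedom shrink
#' rather than imputing p = 1), then combines the per-layer p-values by
#' Fisher's method.
#'
#' @param layer_stats named list (by layer tag) of tibbles `feature_id`,
#'   `z` as from [persistence_stats()].
#' @param membership membership tibble from [map_layers()].
#' @param n_perm,min_members,seed passed to [pathway_pvalue()].
#' @return tibble: `pathway`, one `p_<layer>` column per layer,
#'   `n_layers`, `statistic`, `df`, `p_combined`, `score`
#'   (`-log10(p_combined)`); pathways testable in no layer are dropped.
#' @export
combine_pathway_scores <- function(layer_stats, membership,
                                   n_perm = 10000, min_members = 3,
                                   seed = NULL) {
  pathways <- sort(unique(membership$pathway))
  if (!is.null(seed)) set.seed(seed)
  per_layer <- lapply(names(layer_stats), function(tag) {
    stats <- layer_stats[[tag]]
    mem <- membership[membership$layer == tag, ]
    vapply(pathways, function(pw) {
      pathway_pvalue(stats, mem$feature_id[mem$pathway == pw],
                     n_perm = n_perm, min_members = min_members)
    }, numeric(1))
  })
  names(per_layer) <- names(layer_stats)
  pmat <- do.call(cbind, per_layer)
  res <- lapply(seq_along(pathways), function(i) {
    ps <- pmat[i, ]
    ps <- ps[!is.na(ps)]
    if (length(ps) == 0) return(NULL)
    fc <- fisher_combine(ps)
    row <- tibble(pathway = pathways[i])
    for (tag in names(layer_stats)) row[[paste0("p_", tag)]] <- pmat[i, tag]
    row$n_layers <- fc$k
    row$statistic <- fc$statistic
    row$df <- fc$df
    row$p_combined <- fc$p_value
    row$score <- -log10(fc$p_value)
    row
  })
  dplyr::bind_rows(res)
}

#' Rank pathways under a per-entity assignment cap
#'
#' Overlapping pathways reuse the same measurements, inflating apparent
#' coverage. This step selects a pathway set and an entity-to-pathway
#' assignment that maximize the summed evidence `sum(-log10 p_combined)`
#' over retained pathways, subject to each entity (a layer-tagged data
#' point) being assigned to at most `cap` pathways and each retained
#' pathway keeping at least `min_members` assigned entities. Small
#' instances are solved exactly (subset enumeration with a bipartite
#' feasibility flow); larger ones use a documented greedy pass that
#' processes pathways in decreasing score, claims entities with spare
#' capacity, and drops pathways falling below `min_members`.
#'
#' @param scores tibble with `pathway` and either `score` or `p_combined`.
#' @param membership membership tibble (`entity`, `pathway`) from
#'   [map_layers()].
#' @param cap maximum pathways per entity (default 2).
#' @param min_members minimum entities a retained pathway must keep
#'   (default 3).
#' @param exact_max use the exact regime when there are at most this many
#'   pathways (default 10).
#' @return object of class `assignment_solution`: list with `assignments`
#'   (tibble `entity`, `pathway`), `retained`, `dropped`, `objective`,
#'   `regime` ("exact" or "greedy"), `cap`, `min_members`.
#' @export
dp_rank <- function(scores, membership, cap = 2, min_members = 3,
                    exact_max = 10) {
  if (cap < 1) abort("cap must be >= 1")
  if (!"score" %in% names(scores)) {
    scores$score <- -log10(scores$p_combined)
  }
  mem <- dplyr::semi_join(membership, scores, by = "pathway")
  mem <- dplyr::distinct(mem, .data$entity, .data$pathway)
  pws <- scores$pathway
  sc <- setNames(scores$score, pws)
  regime <- if (length(pws) <= exact_max) "exact" else "greedy"
  sol <- if (regime == "exact") {
    dp_exact(pws, sc, mem, cap, min_members)
  } else {
    dp_greedy(pws, sc, mem, cap, min_members)
  }
  # Fill remaining capacity: retained pathways may keep every member whose
  # entity still has spare cap (deterministic: score desc, then id).
  sol$assignments <- fill_capacity(sol$retained, sc, mem, cap,
                                   sol$assignments)
  structure(
    list(assignments = sol$assignments,
         retained = sol$retained,
         dropped = setdiff(pws, sol$retained),
         objective = unname(sum(sc[sol$retained])),
         regime = regime, cap = cap, min_members = min_members),
    class = "assignment_solution"
  )
}

# Exact regime: enumerate pathway subsets in decreasing objective; the
# first feasible subset (bipartite demand flow) is optimal.
dp_exact <- function(pws, sc, mem, cap, min_members) {
  np <- length(pws)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), np))
  obj <- as.matrix(subsets) %*% sc[pws]
  ord <- order(-obj, rowSums(subsets))
  for (i in ord) {
    keep <- pws[unlist(subsets[i, ])]
    f <- flow_feasible(keep, mem, cap, min_members)
    if (f$feasible) {
      return(list(retained = keep, assignments = f$assignments))
    }
  }
  list(retained = character(),
       assignments = tibble(entity = character(), pathway = character()))
}

# Feasibility of retaining `keep`: every kept pathway must secure
# min_members distinct entities, entities serving <= cap pathways.
# Solved as max flow source -> entity (cap) -> pathway (1) -> sink
# (min_members) by BFS augmenting paths.
flow_feasible <- function(keep, mem, cap, min_members) {
  empty <- tibble(entity = character(), pathway = character())
  if (length(keep) == 0) return(list(feasible = TRUE, assignments = empty))
  mem <- mem[mem$pathway %in% keep, ]
  ents <- sort(unique(mem$entity))
  ne <- length(ents); np <- length(keep)
  need <- np * min_members
  if (ne * cap < need) return(list(feasible = FALSE, assignments = empty))
  n <- 2 + ne + np  # 1 = source, 2..1+ne entities, then pathways, last sink
  capm <- matrix(0, n, n)
  capm[1, 1 + seq_len(ne)] <- cap
  ei <- match(mem$entity, ents)
  pi <- match(mem$pathway, keep)
  capm[cbind(1 + ei, 1 + ne + pi)] <- 1
  capm[1 + ne + seq_len(np), n] <- min_members
  flow <- 0
  repeat {
    # BFS for an augmenting path in the residual graph
    parent <- rep(NA_integer_, n)
    parent[1] <- 0
    queue <- 1L
    while (length(queue) > 0 && is.na(parent[n])) {
      u <- queue[1]; queue <- queue[-1]
      nxt <- which(capm[u, ] > 0 & is.na(parent))
      parent[nxt] <- u
      queue <- c(queue, nxt)
    }
    if (is.na(parent[n])) break
    # bottleneck along the path
    path <- n
    while (path[1] != 1) path <- c(parent[path[1]], path)
    bott <- min(capm[cbind(path[-length(path)], path[-1])])
    for (i in seq_len(length(path) - 1)) {
      u <- path[i]; v <- path[i + 1]
      capm[u, v] <- capm[u, v] - bott
      capm[v, u] <- capm[v, u] + bott
    }
    flow <- flow + bott
    if (flow >= need) break
  }
  if (flow < need) return(list(feasible = FALSE, assignments = empty))
  # residual reverse arcs pathway -> entity encode the assignment
  rev <- which(capm[1 + ne + seq_len(np), 1 + seq_len(ne), drop = FALSE] > 0,
               arr.ind = TRUE)
  assignments <- tibble(entity = ents[rev[, 2]], pathway = keep[rev[, 1]])
  list(feasible = TRUE, assignments = assignments)
}

# Greedy regime: pathways in decreasing score (ties: more members, then
# id); each claims its members with spare capacity or is dropped.
dp_greedy <- function(pws, sc, mem, cap, min_members) {
  sizes <- table(mem$pathway)
  nmem <- setNames(as.integer(sizes[pws]), pws)
  nmem[is.na(nmem)] <- 0L
  ord <- pws[order(-sc[pws], -nmem, pws)]
  used <- new.env(parent = emptyenv())
  retained <- character()
  assign_rows <- list()
  for (pw in ord) {
    cand <- sort(mem$entity[mem$pathway == pw])
    free <- cand[vapply(cand, function(e) {
      (get0(e, envir = used, ifnotfound = 0L)) < cap
    }, logical(1))]
    if (length(free) >= min_members) {
      retained <- c(retained, pw)
      for (e in free) {
        assign(e, get0(e, envir = used, ifnotfound = 0L) + 1L, envir = used)
      }
      assign_rows[[pw]] <- tibble(entity = free, pathway = pw)
    }
  }
  assignments <- if (length(assign_rows) > 0) {
    dplyr::bind_rows(assign_rows)
  } else {
    tibble(entity = character(), pathway = character())
  }
  list(retained = retained, assignments = assignments)
}

# After the retain decision, let retained pathways keep every member whose
# entity still has capacity (does not change the objective; improves the
# explained-data count reported downstream).
fill_capacity <- function(retained, sc, mem, cap, assignments) {
  if (length(retained) == 0) return(assignments)
  used <- table(assignments$entity)
  counts <- new.env(parent = emptyenv())
  for (e in names(used)) assign(e, as.integer(used[[e]]), envir = counts)
  have <- paste(assignments$entity, assignments$pathway)
  ord <- retained[order(-sc[retained], retained)]
  extra <- list()
  for (pw in ord) {
    cand <- sort(setdiff(mem$entity[mem$pathway == pw],
                         assignments$entity[assignments$pathway == pw]))
    for (e in cand) {
      u <- get0(e, envir = counts, ifnotfound = 0L)
      if (u < cap && !(paste(e, pw) %in% have)) {
        assign(e, u + 1L, envir = counts)
        extra[[length(extra) + 1]] <- tibble(entity = e, pathway = pw)
      }
    }
  }
  out <- dplyr::bind_rows(assignments, dplyr::bind_rows(extra))
  dplyr::arrange(out, .data$pathway, .data$entity)
}

#' @export
print.assignment_solution <- function(x, ...) {
  cat("Assignment solution (", x$regime, " regime): ",
      length(x$retained), " pathways retained, objective = ",
      sprintf("%.3f", x$objective), "\n", sep = "")
  invisible(x)
}

#' @rdname dp_rank
#' @param x an `assignment_solution`.
#' @param ... unused.
#' @export
tidy.assignment_solution <- function(x, ...) x$assignments

#' @rdname dp_rank
#' @export
glance.assignment_solution <- function(x, ...) {
  tibble(n_retained = length(x$retained), n_dropped = length(x$dropped),
         objective = x$objective, regime = x$regime, cap = x$cap,
         min_members = x$min_members)
}

#' Ranked pathway report with FDR control
#'
#' Orders pathways by combined p (ascending), breaking ties first by the
#' number of entities the assignment solution retained for the pathway
#' (more explained data ranks higher) and finally lexicographically by
#' id. Benjamini-Hochberg FDR is computed over all testable pathways.
#'
#' @param solution an `assignment_solution` from [dp_rank()].
#' @param scores combined score tibble from [combine_pathway_scores()].
#' @return tibble: scores columns plus `n_entities_retained`, `retained`,
#'   `fdr`, `rank`.
#' @export
rank_report <- function(solution, scores) {
  kept <- table(solution$assignments$pathway)
  out <- scores
  out$n_entities_retained <- as.integer(kept[out$pathway])
  out$n_entities_retained[is.na(out$n_entities_retained)] <- 0L
  out$retained <- out$pathway %in% solution$retained
  out$fdr <- p.adjust(out$p_combined, method = "BH")
  out <- dplyr::arrange(out, .data$p_combined,
                        dplyr::desc(.data$n_entities_retained),
                        .data$pathway)
  out$rank <- seq_len(nrow(out))
  out
}
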