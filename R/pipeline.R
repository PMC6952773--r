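#' Pipeline configuration
#'
#' Bundles every stage parameter and toggle for [run_pipeline()]. All
#' randomness flows from the single `seed`.
#'
#' @param dataset a `multiomics_dataset` (simulated or read from
#'   fixtures with [read_multiomics()]).
#' @param out_dir directory for stage outputs.
#' @param seed master seed for permutations and embeddings.
#' @param min_change,alpha differential-call thresholds.
#' @param n_perm permutations for pathway p-values.
#' @param min_members minimum mapped features per (pathway, layer) and
#'   minimum entities a retained pathway keeps.
#' @param cap maximum pathway assignments per entity.
#' @param perplexity,n_pca,exaggeration,n_runs,max_iter t-SNE stage
#'   parameters.
#' @param stability_min stability threshold for cluster extraction.
#' @param pool_size,max_panel biomarker search parameters.
#' @param biomarker_group sample group for the biomarker search.
#' @param stages named logical vector toggling the optional downstream
#'   stages (`tsne`, `clusters`, `enrichment`, `biomarkers`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(dataset, out_dir, seed = 1,
                            min_change = 0.15, alpha = 0.05,
                            n_perm = 2000, min_members = 3, cap = 2,
                            perplexity = 20, n_pca = 50,
                            exaggeration = 4, n_runs = 15,
                            max_iter = 1000, stability_min = 0.8,
                            pool_size = 10, max_panel = 3,
                            biomarker_group = "fetal",
                            stages = c(tsne = TRUE, clusters = TRUE,
                                       enrichment = TRUE,
                                       biomarkers = TRUE)) {
  cfg <- as.list(environment())
  if (cap < 1) abort("cap must be >= 1")
  structure(cfg, class = "pipeline_config")
}

stage_names <- c("normalize", "filter", "differential", "map",
                 "pathway_p", "fisher", "dp_rank", "tsne", "clusters",
                 "enrichment", "biomarkers")

#' Run the full integration pipeline
#'
#' Executes normalize -> singlet filter -> differential statistics ->
#' pathway mapping -> per-layer pathway p-values -> Fisher combination ->
#' capped-assignment ranking -> t-SNE embedding -> outlier-cluster
#' extraction -> annotation enrichment -> biomarker panel search, writing
#' every intermediate as a commented TSV and a JSON manifest with
#' parameters, seed and per-file checksums. Reruns with the same
#' configuration reproduce identical checksums.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result`: list with `manifest` (tibble: `stage`,
#'   `enabled`, `file`, `md5`), `report` (ranked pathway table),
#'   `clusters`, `enrichment`, `biomarkers`, `scores`, `solution`,
#'   `embedding`, paths and the config.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ds <- config$dataset
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  par_hash <- tools::md5sum(
    files = write_param_file(config, file.path(dir, "parameters.json")))
  hdr <- c(paste0("triomix ",
                  as.character(utils::packageVersion("triomix"))),
           paste0("seed=", config$seed),
           paste0("params=", unname(par_hash)))
  outfile <- function(stage, name) file.path(dir, paste0(name, ".tsv"))
  files <- list()
  note <- function(stage, path) {
    files[[length(files) + 1]] <<- tibble(stage = stage, file = path)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", stage, "' failed: ",
                   conditionMessage(e)))
    })
  }
  enabled <- function(st) {
    !(st %in% names(config$stages)) || isTRUE(config$stages[[st]])
  }

  # 1. normalize
  layers <- run_stage("normalize", lapply(ds$layers, tic_normalize))
  for (tag in names(layers)) {
    f <- outfile("normalize", paste0(tag, "_normalized"))
    write_omics_matrix(layers[[tag]], f, header = hdr)
    note("normalize", f)
  }

  # 2. singlet filter (protein layer)
  layers$protein <- run_stage("filter", filter_singletons(layers$protein))
  f <- outfile("filter", "protein_filtered")
  write_omics_matrix(layers$protein, f, header = hdr)
  note("filter", f)

  # 3. differential + persistence statistics per layer
  stats <- run_stage("differential", lapply(layers, function(l) {
    persistence_stats(l, ds$metadata)
  }))
  diffs <- run_stage("differential", lapply(layers, function(l) {
    differential_test(l, ds$metadata, min_change = config$min_change,
                      alpha = config$alpha)
  }))
  for (tag in names(diffs)) {
    f <- outfile("differential", paste0(tag, "_differential"))
    write_omics_matrix(dplyr::left_join(diffs[[tag]], stats[[tag]],
                                        by = "feature_id"),
                       f, header = hdr)
    note("differential", f)
  }

  # 4. map layers to pathways / gene clusters
  mapped <- run_stage("map", map_layers(layers, ds$pathway_db,
                                        ds$gene_cluster_map))
  f <- outfile("map", "membership")
  write_omics_matrix(mapped$membership, f, header = hdr)
  note("map", f)

  # 5 + 6. per-layer pathway p-values and Fisher combination
  scores <- run_stage("pathway_p", combine_pathway_scores(
    stats, mapped$membership, n_perm = config$n_perm,
    min_members = config$min_members, seed = config$seed))
  f <- outfile("fisher", "pathway_scores")
  write_omics_matrix(scores, f, header = hdr)
  note("pathway_p", f)
  note("fisher", f)

  # 7. capped-assignment ranking and report
  solution <- run_stage("dp_rank", dp_rank(
    scores, mapped$membership, cap = config$cap,
    min_members = config$min_members))
  report <- rank_report(solution, scores)
  f <- outfile("dp_rank", "pathway_report")
  write_omics_matrix(report, f, header = hdr)
  note("dp_rank", f)
  jsonlite::write_json(
    split(solution$assignments$pathway, solution$assignments$entity),
    file.path(dir, "assignments.json"))
  note("dp_rank", file.path(dir, "assignments.json"))

  embedding <- NULL; clusters <- NULL; enrichment <- NULL
  biomarkers <- NULL

  # 8. t-SNE on standardized cross-layer gene profiles
  if (enabled("tsne")) {
    profiles <- run_stage("tsne", gene_profiles(layers))
    embedding <- run_stage("tsne", tsne_embed(
      profiles, perplexity = config$perplexity, n_pca = config$n_pca,
      exaggeration = config$exaggeration, n_runs = config$n_runs,
      base_seed = config$seed, max_iter = config$max_iter))
    f <- outfile("tsne", "tsne_coordinates")
    write_omics_matrix(embedding$coords, f, header = hdr)
    note("tsne", f)
  }

  # 9. consensus outlier clusters, directed by fetal-vs-adult means
  if (enabled("clusters") && !is.null(embedding)) {
    direction <- fetal_adult_direction(layers, ds$metadata)
    clusters <- run_stage("clusters", suppressWarnings(
      extract_outlier_clusters(embedding, direction,
                               stability_min = config$stability_min)))
    f <- outfile("clusters", "consensus_clusters")
    write_omics_matrix(clusters$assignment, f, header = hdr)
    note("clusters", f)
  }

  # 10. annotation enrichment of the outlier-cluster genes
  if (enabled("enrichment") && !is.null(clusters)) {
    universe <- intersect(layers$transcript$feature_id,
                          layers$protein$feature_id)
    query <- intersect(
      clusters$assignment$feature_id[
        clusters$assignment$label != "background"], universe)
    enrichment <- if (length(query) > 0) {
      run_stage("enrichment", enrich(query, ds$annotation_db, universe))
    } else {
      enrich(character(0), ds$annotation_db, universe)
    }
    f <- outfile("enrichment", "enrichment")
    write_omics_matrix(enrichment, f, header = hdr)
    note("enrichment", f)
  }

  # 11. biomarker panel search on the protein layer
  if (enabled("biomarkers")) {
    biomarkers <- run_stage("biomarkers", search_panels(
      layers$protein, ds$metadata, group = config$biomarker_group,
      pool_size = config$pool_size, max_panel = config$max_panel))
    f <- outfile("biomarkers", "biomarker_panels")
    write_omics_matrix(biomarkers$panels, f, header = hdr)
    note("biomarkers", f)
  }

  file_tbl <- dplyr::bind_rows(files)
  file_tbl$md5 <- unname(tools::md5sum(file_tbl$file))
  manifest <- dplyr::left_join(
    tibble(stage = stage_names,
           enabled = vapply(stage_names, enabled, logical(1))),
    file_tbl, by = "stage")
  jsonlite::write_json(
    list(seed = config$seed, params_md5 = unname(par_hash),
         stages = manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  structure(
    list(manifest = manifest, report = report, scores = scores,
         membership = mapped$membership,
         solution = solution, embedding = embedding, clusters = clusters,
         enrichment = enrichment, biomarkers = biomarkers,
         stats = stats, out_dir = dir, config = config),
    class = "pipeline_result"
  )
}

# Integrated feature profiles for the embedding stage: genes quantified
# in both the transcript and protein layer, each layer's log2 row
# z-scored and the two sample vectors concatenated.
gene_profiles <- function(layers) {
  shared <- intersect(layers$transcript$feature_id,
                      layers$protein$feature_id)
  zrow <- function(layer) {
    m <- safe_log2(layer_matrix(layer))[shared, , drop = FALSE]
    sds <- sqrt(row_vars(m))
    sds[sds == 0] <- 1
    (m - rowMeans(m)) / sds
  }
  zt <- zrow(layers$transcript)
  zp <- zrow(layers$protein)
  colnames(zt) <- paste0("tr_", colnames(zt))
  colnames(zp) <- paste0("pr_", colnames(zp))
  m <- cbind(zt, zp)
  dplyr::bind_cols(tibble(feature_id = shared),
                   as_tibble(m, rownames = NULL))
}

# Mean fetal-minus-adult log2 intensity per gene (transcript + protein
# averaged), used to direct outlier clusters.
fetal_adult_direction <- function(layers, metadata) {
  shared <- intersect(layers$transcript$feature_id,
                      layers$protein$feature_id)
  one <- function(layer) {
    m <- safe_log2(layer_matrix(layer, metadata))[shared, , drop = FALSE]
    fet <- metadata$sample_id[metadata$group == "fetal"]
    adu <- metadata$sample_id[metadata$group != "fetal"]
    rowMeans(m[, fet, drop = FALSE]) - rowMeans(m[, adu, drop = FALSE])
  }
  d <- (one(layers$transcript) + one(layers$protein)) / 2
  tibble(feature_id = shared, direction = unname(d))
}

write_param_file <- function(config, path) {
  pars <- config[setdiff(names(config), c("dataset", "out_dir"))]
  jsonlite::write_json(pars, path, auto_unbox = TRUE, digits = NA)
  path
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:", sum(x$manifest$enabled[!duplicated(x$manifest$stage)]),
      "of", length(stage_names), "stages enabled; outputs in",
      x$out_dir, "\n")
  cat("Top pathways:\n")
  print(head(x$report[c("pathway", "p_combined", "fdr", "rank",
                        "n_entities_retained")], 5))
  invisible(x)
}
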