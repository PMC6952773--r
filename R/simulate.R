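#' Configuration for the synthetic multi-omics generator
#'
#' Defines the simulated study: three sample groups (fetal, adult male,
#' adult female), two conditions (normoxia, hypoxia) with `n_replicates`
#' per cell, three quantitative layers over a shared gene/metabolite
#' universe, and a planted module perturbed coherently — same sign in
#' every group and layer — by the condition. Half of the planted module
#' is additionally elevated in fetal samples and half suppressed, so the
#' embedding stage sees two separated clusters with opposite
#' developmental directions. One decoy pathway overlapping the planted
#' module by 50% is always generated to exercise assignment capping.
#'
#' @param n_replicates replicates per (group, condition) cell (>= 2;
#'   default 5).
#' @param n_genes total genes (default 500).
#' @param n_metabolites total metabolites (default 120).
#' @param n_pathways total pathways including planted and decoy
#'   (default 15).
#' @param module_genes genes in the planted module (default 40).
#' @param module_metabolites metabolites in the planted module
#'   (default 10).
#' @param effect_log2 planted condition effect, log2 scale (default 1).
#' @param dev_effect_log2 planted fetal-vs-adult effect, log2 scale,
#'   applied +/- to the two module halves (default 1).
#' @param noise_sd replicate noise sd on the log2 scale (> 0;
#'   default 0.25).
#' @param singlet_fraction fraction of background proteins carrying a
#'   single unique peptide (default 0.2).
#' @param n_annotation_terms annotation terms besides the planted term
#'   (default 30).
#' @param n_transcript_seqs,n_reference_proteins sequence fixture sizes
#'   (defaults 40 and 50).
#' @param seed RNG seed; identical seeds give identical datasets.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_replicates = 5, n_genes = 500,
                              n_metabolites = 120, n_pathways = 15,
                              module_genes = 40, module_metabolites = 10,
                              effect_log2 = 1, dev_effect_log2 = 1,
                              noise_sd = 0.25, singlet_fraction = 0.2,
                              n_annotation_terms = 30,
                              n_transcript_seqs = 40,
                              n_reference_proteins = 50, seed = 1) {
  cfg <- as.list(environment())
  if (n_replicates < 2) abort("n_replicates must be >= 2")
  if (noise_sd <= 0) abort("noise_sd must be > 0")
  counts <- c(n_genes, n_metabolites, n_pathways, module_genes,
              module_metabolites, n_annotation_terms)
  if (any(counts <= 0)) abort("counts must be positive")
  if (module_genes > n_genes || module_metabolites > n_metabolites) {
    abort("planted module must fit inside the feature universe")
  }
  if (n_pathways < 3) abort("need at least 3 pathways (planted + decoy + 1)")
  structure(cfg, class = "simulation_config")
}

#' Simulate a multi-omics dataset with a planted module
#'
#' Generates transcript, protein and metabolite layers over identical
#' samples, plus the pathway/annotation/cluster maps and sequence
#' fixtures the pipeline consumes. Intensities follow a multiplicative
#' log-normal noise model: `log2` intensity = feature baseline + planted
#' effects + `N(0, noise_sd)`; transcripts are rounded to counts. Null
#' features carry zero effect everywhere. Singlet unique-peptide counts
#' are planted only on background proteins so the module stays fully
#' quantified after filtering.
#'
#' @param config a [simulation_config()].
#' @return a `multiomics_dataset` list: `layers` (named list of layer
#'   tibbles), `metadata`, `pathway_db`, `annotation_db`,
#'   `gene_cluster_map`, `transcript_seqs`, `reference_proteome`,
#'   `truth` (planted ids, pathway/term/decoy names, effects), `config`.
#' @export
simulate_multiomics <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  mets <- sprintf("m%03d", seq_len(config$n_metabolites))
  module_g <- genes[seq_len(config$module_genes)]
  module_m <- mets[seq_len(config$module_metabolites)]
  half <- ceiling(length(module_g) / 2)
  up_fetal <- module_g[seq_len(half)]
  down_fetal <- setdiff(module_g, up_fetal)

  groups <- c("fetal", "adult_male", "adult_female")
  conditions <- c("normoxia", "hypoxia")
  metadata <- tidyr::expand_grid(group = groups, condition = conditions,
                                 rep = seq_len(config$n_replicates))
  metadata$sample_id <- sprintf("%s_%s_%d", metadata$group,
                                substr(metadata$condition, 1, 2),
                                metadata$rep)
  metadata <- metadata[c("sample_id", "group", "condition")]

  gen_layer <- function(features, module, fetal_dir) {
    base <- runif(length(features), min = 6, max = 12)
    eff <- ifelse(features %in% module, config$effect_log2, 0)
    dev <- numeric(length(features))
    if (!is.null(fetal_dir)) {
      dev[features %in% fetal_dir$up] <- config$dev_effect_log2
      dev[features %in% fetal_dir$down] <- -config$dev_effect_log2
    }
    m <- matrix(0, nrow = length(features), ncol = nrow(metadata),
                dimnames = list(features, metadata$sample_id))
    hyp <- metadata$condition == "hypoxia"
    fet <- metadata$group == "fetal"
    for (j in seq_len(nrow(metadata))) {
      mu <- base + eff * hyp[j] + dev * fet[j]
      m[, j] <- 2^(mu + rnorm(length(features), sd = config$noise_sd))
    }
    m
  }

  fetal_dir <- list(up = up_fetal, down = down_fetal)
  tr <- gen_layer(genes, module_g, fetal_dir)
  tr[] <- round(tr)  # transcript abundances are counts
  pr <- gen_layer(genes, module_g, fetal_dir)
  mb <- gen_layer(mets, module_m, NULL)

  to_tbl <- function(m) {
    dplyr::bind_cols(tibble(feature_id = rownames(m)), as_tibble(m))
  }
  transcript <- to_tbl(tr)
  protein <- to_tbl(pr)
  background <- setdiff(genes, module_g)
  n_singlet <- round(config$singlet_fraction * length(background))
  singlets <- sample(background, n_singlet)
  protein$unique_peptides <- ifelse(
    protein$feature_id %in% singlets, 1L,
    sample(2:12, config$n_genes, replace = TRUE))
  metabolite <- to_tbl(mb)

  # pathways: planted, 50%-overlap decoy, then random background sets
  nonmod_g <- setdiff(genes, module_g)
  nonmod_m <- setdiff(mets, module_m)
  overlap <- module_g[seq_len(floor(length(module_g) / 2))]
  decoy <- c(overlap, sample(nonmod_g, length(overlap)))
  others <- lapply(seq_len(config$n_pathways - 2), function(i) {
    ng <- sample(10:25, 1)
    nm <- sample(2:5, 1)
    c(sample(nonmod_g, ng), sample(nonmod_m, nm))
  })
  pathway_db <- tibble(
    term = c("pw_planted", "pw_decoy",
             sprintf("pw%02d", seq_len(config$n_pathways - 2))),
    description = c("planted mitochondrion-like module",
                    "decoy overlapping the planted module by 50%",
                    rep("background pathway", config$n_pathways - 2)),
    members = c(list(c(module_g, module_m)), list(decoy), others)
  )

  ann_others <- lapply(seq_len(config$n_annotation_terms), function(i) {
    sample(nonmod_g, sample(10:50, 1))
  })
  annotation_db <- tibble(
    term = c("term_planted",
             sprintf("term%03d", seq_len(config$n_annotation_terms))),
    description = c("planted mitochondrion-like annotation",
                    rep("background annotation",
                        config$n_annotation_terms)),
    members = c(list(module_g), ann_others)
  )

  # gene clusters: mostly singleton clusters, some random pairs
  cluster <- paste0("cl_", genes)
  n_pairs <- floor(config$n_genes / 20)
  pair_pool <- sample(nonmod_g, 2 * n_pairs)
  for (i in seq_len(n_pairs)) {
    a <- pair_pool[2 * i - 1]; b <- pair_pool[2 * i]
    cluster[genes == b] <- cluster[genes == a]
  }
  gene_cluster_map <- tibble(gene = genes, cluster = cluster)

  seqs <- simulate_sequences(config$n_transcript_seqs,
                             config$n_reference_proteins)

  structure(
    list(layers = list(transcript = transcript, protein = protein,
                       metabolite = metabolite),
         metadata = metadata, pathway_db = pathway_db,
         annotation_db = annotation_db,
         gene_cluster_map = gene_cluster_map,
         transcript_seqs = seqs$transcripts,
         reference_proteome = seqs$proteins,
         truth = list(module_genes = module_g,
                      module_metabolites = module_m,
                      up_fetal = up_fetal, down_fetal = down_fetal,
                      planted_pathway = "pw_planted",
                      decoy_pathway = "pw_decoy",
                      planted_term = "term_planted",
                      singlets = singlets,
                      encoded_proteins = seqs$encoded,
                      effect_log2 = config$effect_log2),
         config = config),
    class = "multiomics_dataset"
  )
}

# Sequence fixtures: a reference proteome in which ~60% of proteins are
# exactly encoded (random codons) inside a transcript, on a random strand
# and frame, and the rest are unrelated random sequences.
simulate_sequences <- function(n_transcripts, n_proteins) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  nts <- c("A", "C", "G", "T")
  codons <- aa_codon_table()
  rand_dna <- function(n) paste(sample(nts, n, replace = TRUE),
                                collapse = "")
  n_encoded <- min(floor(0.6 * n_proteins), n_transcripts)
  proteins <- character(n_proteins)
  names(proteins) <- sprintf("prot%03d", seq_len(n_proteins))
  transcripts <- character(n_transcripts)
  names(transcripts) <- sprintf("tx%03d", seq_len(n_transcripts))
  encoded <- names(proteins)[seq_len(n_encoded)]
  for (i in seq_len(n_proteins)) {
    proteins[i] <- paste(sample(aa, sample(80:150, 1), replace = TRUE),
                         collapse = "")
  }
  for (i in seq_len(n_transcripts)) {
    if (i <= n_encoded) {
      cds <- paste(vapply(strsplit(proteins[i], "")[[1]],
                          function(a) sample(codons[[a]], 1), ""),
                   collapse = "")
      lead <- rand_dna(3 * sample(5:15, 1))
      tail <- rand_dna(3 * sample(5:15, 1))
      s <- paste0(lead, cds, tail)
      if (runif(1) < 0.5) {
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s)))
      }
      transcripts[i] <- s
    } else {
      transcripts[i] <- rand_dna(3 * sample(100:200, 1))
    }
  }
  list(transcripts = transcripts, proteins = proteins, encoded = encoded)
}

# Codons per amino acid under the standard table (used for random
# reverse translation; stop codons excluded).
aa_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))[setdiff(unique(unname(gc)), "*")]
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat("Synthetic multi-omics dataset:",
      nrow(x$layers$transcript), "genes,",
      nrow(x$layers$metabolite), "metabolites,",
      nrow(x$metadata), "samples,",
      nrow(x$pathway_db), "pathways (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Write a simulated dataset to plain-text fixtures
#'
#' Writes three matrix TSVs, the sample metadata, two GMT files, the
#' gene-cluster map and two FASTA files into `dir`.
#'
#' @param dataset a `multiomics_dataset`.
#' @param dir output directory (created if missing).
#' @return tibble manifest: `file`, `type`.
#' @export
write_multiomics <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_omics_matrix(dataset$layers$transcript, p("transcript_matrix.tsv"))
  write_omics_matrix(dataset$layers$protein, p("protein_matrix.tsv"))
  write_omics_matrix(dataset$layers$metabolite, p("metabolite_matrix.tsv"))
  readr::write_tsv(dataset$metadata, p("metadata.tsv"), progress = FALSE)
  write_gmt(dataset$pathway_db, p("pathways.gmt"))
  write_gmt(dataset$annotation_db, p("annotations.gmt"))
  readr::write_tsv(dataset$gene_cluster_map, p("gene_clusters.tsv"),
                   progress = FALSE)
  write_fasta(dataset$transcript_seqs, p("transcripts.fasta"))
  write_fasta(dataset$reference_proteome, p("reference_proteome.fasta"))
  tibble(
    file = c("transcript_matrix.tsv", "protein_matrix.tsv",
             "metabolite_matrix.tsv", "metadata.tsv", "pathways.gmt",
             "annotations.gmt", "gene_clusters.tsv", "transcripts.fasta",
             "reference_proteome.fasta"),
    type = c("matrix", "matrix", "matrix", "metadata", "gmt", "gmt",
             "map", "fasta", "fasta")
  )
}

#' Read a multi-omics dataset from fixture files
#'
#' Inverse of [write_multiomics()] (the planted-truth record is not part
#' of the file contract and is absent after a round trip).
#'
#' @param dir directory holding the fixture files.
#' @return a `multiomics_dataset` (with `truth` and `config` `NULL`).
#' @export
read_multiomics <- function(dir) {
  p <- function(f) {
    fp <- file.path(dir, f)
    if (!file.exists(fp)) abort(paste0("missing fixture file: ", fp))
    fp
  }
  structure(
    list(layers = list(
           transcript = read_omics_matrix(p("transcript_matrix.tsv")),
           protein = read_omics_matrix(p("protein_matrix.tsv")),
           metabolite = read_omics_matrix(p("metabolite_matrix.tsv"))),
         metadata = read_metadata(p("metadata.tsv")),
         pathway_db = read_gmt(p("pathways.gmt")),
         annotation_db = read_gmt(p("annotations.gmt")),
         gene_cluster_map = read_gene_clusters(p("gene_clusters.tsv")),
         transcript_seqs = read_fasta(p("transcripts.fasta"), "dna"),
         reference_proteome = read_fasta(p("reference_proteome.fasta"),
                                         "aa"),
         truth = NULL, config = NULL),
    class = "multiomics_dataset"
  )
}
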