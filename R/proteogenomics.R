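#' Six-frame in silico translation
#'
#' Translates a nucleotide sequence in all three reading frames of both
#' strands and returns every maximal stop-free stretch (ORFs are
#' stop-to-stop; no initiator methionine is required, so all possible
#' encoded peptides are enumerated). Codons containing `N` translate to
#' `X`. Offsets locate each ORF on the forward strand of the input,
#' 0-based and half-open.
#'
#' @param dna a single nucleotide sequence (A/C/G/T/N), or a named
#'   character vector of sequences.
#' @param min_orf_len minimum ORF length in amino acids (default 20;
#'   shorter fragments are below peptide-evidence scale).
#' @return tibble: `transcript`, `frame` (+1..+3, -1..-3), `start`,
#'   `end`, `peptide`.
#' @export
six_frame_translate <- function(dna, min_orf_len = 20) {
  if (min_orf_len < 1) abort("min_orf_len must be >= 1")
  if (is.null(names(dna))) {
    names(dna) <- if (length(dna) == 1) "seq1" else
      paste0("seq", seq_along(dna))
  }
  bad <- grepl("[^ACGTNacgtn]", dna)
  if (any(bad)) {
    abort(paste0("sequence contains characters outside {A,C,G,T,N}: ",
                 paste(names(dna)[bad], collapse = ", ")))
  }
  dna <- toupper(dna)
  empty <- tibble(transcript = character(), frame = integer(),
                  start = integer(), end = integer(),
                  peptide = character())
  long <- dna[nchar(dna) >= 3]
  if (length(long) == 0) return(empty)
  fwd <- Biostrings::DNAStringSet(long)
  rev <- Biostrings::reverseComplement(fwd)
  L <- nchar(long)
  res <- list()
  # one batched translation per (strand, frame): 6 calls total
  for (strand in c(1L, -1L)) {
    src_all <- if (strand == 1L) fwd else rev
    for (f in 1:3) {
      naa <- (L - (f - 1)) %/% 3
      ok <- which(naa >= 1)
      if (length(ok) == 0) next
      sub <- Biostrings::subseq(src_all[ok], start = f,
                                width = naa[ok] * 3)
      aas <- as.character(suppressWarnings(
        Biostrings::translate(sub, if.fuzzy.codon = "X",
                              no.init.codon = TRUE)))
      for (j in seq_along(ok)) {
        orfs <- split_orfs(aas[j], min_orf_len)
        if (nrow(orfs) == 0) next
        # aa-coordinates -> nt coordinates on the translated strand
        nt_start <- (f - 1) + 3 * orfs$aa_start
        nt_end <- (f - 1) + 3 * orfs$aa_end
        if (strand == -1L) {  # map back to the forward strand
          Lj <- L[ok[j]]
          tmp <- Lj - nt_end
          nt_end <- Lj - nt_start
          nt_start <- tmp
        }
        res[[length(res) + 1]] <- tibble(
          transcript = names(long)[ok[j]], frame = strand * f,
          start = as.integer(nt_start), end = as.integer(nt_end),
          peptide = orfs$peptide
        )
      }
    }
  }
  if (length(res) == 0) return(empty)
  out <- dplyr::bind_rows(res)
  dplyr::arrange(out, .data$transcript, .data$frame, .data$start)
}

# Maximal stop-free stretches of a translated frame; 0-based half-open
# amino-acid coordinates within the frame.
split_orfs <- function(aa, min_orf_len) {
  parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
  if (length(parts) == 0) {
    return(tibble(aa_start = integer(), aa_end = integer(),
                  peptide = character()))
  }
  lens <- nchar(parts)
  # start of segment i = sum of previous lengths + number of stops passed
  starts <- cumsum(c(0L, lens[-length(lens)] + 1L))
  keep <- lens >= min_orf_len
  tibble(aa_start = starts[keep], aa_end = starts[keep] + lens[keep],
         peptide = parts[keep])
}

#' Build a transcript-evidence-filtered custom proteome database
#'
#' Six-frame translates the transcripts and retains exactly those
#' reference proteins that share an exact ungapped amino-acid substring
#' of length at least `min_match_len` with some ORF — the transcript-level
#' evidence criterion. Proteins without any such evidence are removed,
#' yielding a custom reference proteome restricted to what the
#' transcriptome can encode.
#'
#' @param transcripts named character vector of nucleotide sequences.
#' @param reference_proteome named character vector of amino-acid
#'   sequences.
#' @param min_orf_len minimum ORF length (aa) for translation.
#' @param min_match_len minimum exact shared substring (aa) counting as
#'   evidence (default 30).
#' @return object of class `custom_proteome_db`: list with `report`
#'   (tibble: `protein_id`, `status` retained/removed, `match_length`,
#'   `transcript_id`, `match_start`, `match_end` — span on the protein,
#'   0-based half-open), `retained` (named character vector of retained
#'   sequences), and the parameters.
#' @export
build_custom_db <- function(transcripts, reference_proteome,
                            min_orf_len = 20, min_match_len = 30) {
  if (length(transcripts) == 0) abort("empty transcript set")
  if (length(reference_proteome) == 0) abort("empty reference proteome")
  if (is.null(names(reference_proteome))) {
    names(reference_proteome) <- paste0("prot", seq_along(reference_proteome))
  }
  orfs <- six_frame_translate(transcripts, min_orf_len = min_orf_len)
  k <- min_match_len
  # k-mer index over all ORF peptides -> (orf row, offset)
  kmer_orf <- list()
  if (nrow(orfs) > 0) {
    long <- which(nchar(orfs$peptide) >= k)
    kl <- lapply(long, function(i) {
      p <- orfs$peptide[i]
      starts <- seq_len(nchar(p) - k + 1)
      tibble(kmer = substring(p, starts, starts + k - 1),
             orf = i, offset = starts - 1L)
    })
    kmer_tab <- dplyr::bind_rows(kl)
  } else {
    kmer_tab <- tibble(kmer = character(), orf = integer(),
                       offset = integer())
  }
  kmer_env <- new.env(parent = emptyenv(), size = max(nrow(kmer_tab), 16))
  if (nrow(kmer_tab) > 0) {
    # keep the first occurrence per k-mer; any witness suffices
    first <- !duplicated(kmer_tab$kmer)
    ktab <- kmer_tab[first, ]
    for (i in seq_len(nrow(ktab))) {
      assign(ktab$kmer[i], c(ktab$orf[i], ktab$offset[i]), envir = kmer_env)
    }
  }
  rows <- imap(reference_proteome, function(p, id) {
    match_protein(p, id, k, kmer_env, orfs)
  })
  report <- dplyr::bind_rows(rows)
  structure(
    list(report = report,
         retained = reference_proteome[
           report$protein_id[report$status == "retained"]],
         min_orf_len = min_orf_len, min_match_len = min_match_len),
    class = "custom_proteome_db"
  )
}

# Scan one protein's k-mers against the ORF index; on a hit, extend the
# match maximally in both directions and record the span.
match_protein <- function(p, id, k, kmer_env, orfs) {
  np <- nchar(p)
  if (np >= k) {
    for (s in seq_len(np - k + 1)) {
      hit <- get0(substring(p, s, s + k - 1), envir = kmer_env)
      if (!is.null(hit)) {
        orf_seq <- orfs$peptide[hit[1]]
        po <- s - 1L           # 0-based start on protein
        oo <- hit[2]           # 0-based start on ORF
        left <- 0L
        while (po - left > 0 && oo - left > 0 &&
               substring(p, po - left, po - left) ==
               substring(orf_seq, oo - left, oo - left)) {
          left <- left + 1L
        }
        right <- k
        while (po + right < np && oo + right < nchar(orf_seq) &&
               substring(p, po + right + 1, po + right + 1) ==
               substring(orf_seq, oo + right + 1, oo + right + 1)) {
          right <- right + 1L
        }
        return(tibble(protein_id = id, status = "retained",
                      match_length = left + right,
                      transcript_id = orfs$transcript[hit[1]],
                      match_start = po - left,
                      match_end = po + right))
      }
    }
  }
  tibble(protein_id = id, status = "removed", match_length = 0L,
         transcript_id = NA_character_,
         match_start = NA_integer_, match_end = NA_integer_)
}

#' @export
print.custom_proteome_db <- function(x, ...) {
  n <- nrow(x$report)
  cat("Custom proteome database:", sum(x$report$status == "retained"),
      "of", n, "reference proteins retained",
      sprintf("(min match %d aa)\n", x$min_match_len))
  invisible(x)
}

#' @rdname build_custom_db
#' @param x a `custom_proteome_db`.
#' @param ... unused.
#' @export
tidy.custom_proteome_db <- function(x, ...) x$report
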