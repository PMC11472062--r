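#' Normalize a nucleotide sequence to the DNA alphabet
#'
#' Uppercases the input and maps U to T so that RNA-alphabet references
#' (e.g. database tRNA entries) and DNA reads share one canonical alphabet.
#' IUPAC ambiguity codes are rejected rather than expanded: probe design and
#' edit-distance computations require concrete sequences.
#'
#' @param raw Character vector of sequences over `{A,C,G,T,U}` (any case).
#' @return Character vector over `{A,C,G,T}`.
#' @examples
#' normalize_sequence("acgu")  # "ACGT"
#' @export
normalize_sequence <- function(raw) {
  if (!is.character(raw)) {
    dorq_error("sequences must be supplied as a character vector", "dorq_type_error")
  }
  up <- chartr("U", "T", toupper(raw))
  bad <- grepl("[^ACGT]", up)
  if (any(bad)) {
    offend <- gsub("[ACGT]", "", up[bad][1L])
    ch <- substr(offend, 1L, 1L)
    if (ch %in% c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")) {
      dorq_error(
        sprintf("ambiguity code '%s' not allowed: references must be unambiguous", ch),
        "dorq_ambiguous_base_error"
      )
    }
    dorq_error(sprintf("non-nucleotide character '%s' in sequence", ch),
               "dorq_alphabet_error")
  }
  up
}

#' Reverse complement of DNA sequences
#'
#' @param seq Character vector of normalized DNA sequences.
#' @return Character vector of Watson-Crick reverse complements.
#' @examples
#' reverse_complement("GATTACA")  # "TGTAATC"
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_sequence(seq)
  if (length(seq) == 0L) return(character(0L))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and substitutions
#' converting `a` into `b`. Elementwise over recycled vectors; use
#' [levenshtein_matrix()] for all pairs.
#'
#' @param a,b Character vectors of normalized sequences.
#' @return Integer vector of distances.
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- as.integer(adist(a[i], b[i]))
  out
}

#' All-pairs Levenshtein distance matrix
#'
#' @param a Character vector (rows).
#' @param b Character vector (columns); defaults to `a`.
#' @return Integer matrix of pairwise edit distances.
#' @export
levenshtein_matrix <- function(a, b = a) {
  m <- adist(a, b)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(names(a), names(b))
  m
}

#' GC fraction of sequences
#'
#' @param seq Character vector of DNA sequences.
#' @return Numeric vector in `[0, 1]`.
#' @export
gc_fraction <- function(seq) {
  nchar(gsub("[^GCgc]", "", seq)) / nchar(seq)
}

# ---- tRNA reference collections -------------------------------------------

VALID_COMPARTMENTS <- c("cytosolic", "mitochondrial")

#' Construct a tRNA reference collection
#'
#' A reference collection holds mature tRNA sequences (5'->3', DNA alphabet
#' after normalization) with compartment, amino-acid and anticodon annotation.
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of mature sequences (>= 40 nt each).
#' @param organism Organism label (recycled).
#' @param compartment `"cytosolic"` or `"mitochondrial"` (recycled).
#' @param amino_acid One-letter amino-acid codes (recycled).
#' @param anticodon 3-mer anticodons (recycled).
#' @return A `dorq_references` data frame.
#' @export
trna_references <- function(id, sequence, organism = NA_character_,
                            compartment = NA_character_,
                            amino_acid = NA_character_,
                            anticodon = NA_character_) {
  sequence <- normalize_sequence(sequence)
  if (anyDuplicated(id)) {
    dorq_error("reference ids must be unique within a collection", "dorq_duplicate_id_error")
  }
  if (any(nchar(sequence) < 40L)) {
    dorq_error("mature tRNA references must be at least 40 nt", "dorq_sequence_too_short_error")
  }
  ok <- is.na(compartment) | compartment %in% VALID_COMPARTMENTS
  if (!all(ok)) {
    dorq_error("compartment must be 'cytosolic' or 'mitochondrial'", "dorq_compartment_error")
  }
  n <- length(id)
  out <- data.frame(
    id = as.character(id),
    organism = rep_len(as.character(organism), n),
    compartment = rep_len(as.character(compartment), n),
    amino_acid = rep_len(as.character(amino_acid), n),
    anticodon = rep_len(as.character(anticodon), n),
    sequence = sequence,
    stringsAsFactors = FALSE
  )
  class(out) <- c("dorq_references", "data.frame")
  out
}

#' @export
print.dorq_references <- function(x, ...) {
  cat(sprintf("tRNA reference collection: %d sequences (%d cytosolic, %d mitochondrial)\n",
              nrow(x),
              sum(x$compartment == "cytosolic", na.rm = TRUE),
              sum(x$compartment == "mitochondrial", na.rm = TRUE)))
  cat(sprintf("lengths %d-%d nt\n", min(nchar(x$sequence)), max(nchar(x$sequence))))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more\n", nrow(x) - 6L))
  invisible(x)
}

#' Read tRNA references from FASTA
#'
#' Headers follow `>id|organism|compartment|aa|anticodon`; headers carrying
#' only an id are accepted when annotations are supplied through a sidecar
#' table (TSV with columns `id`, `organism`, `compartment`, `amino_acid`,
#' `anticodon`) or left missing. RNA-alphabet sequences are converted to DNA.
#'
#' @param path FASTA file (gzip transparent).
#' @param annotations Optional path to a sidecar TSV, or a data frame.
#' @return A `dorq_references` collection.
#' @export
read_trna_references <- function(path, annotations = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) dorq_error("no sequences in FASTA", "dorq_empty_input_error")
  headers <- names(set)
  parts <- strsplit(headers, "|", fixed = TRUE)
  full <- all(lengths(parts) == 5L)
  if (full) {
    f <- do.call(rbind, parts)
    refs <- trna_references(
      id = f[, 1L], sequence = as.character(set), organism = f[, 2L],
      compartment = f[, 3L], amino_acid = f[, 4L], anticodon = f[, 5L]
    )
  } else {
    ids <- vapply(strsplit(headers, "[| \t]"), `[`, character(1L), 1L)
    refs <- trna_references(id = ids, sequence = as.character(set))
    if (!is.null(annotations)) {
      ann <- if (is.character(annotations)) {
        read.delim(annotations, stringsAsFactors = FALSE)
      } else {
        as.data.frame(annotations, stringsAsFactors = FALSE)
      }
      m <- match(refs$id, ann$id)
      for (col in intersect(c("organism", "compartment", "amino_acid", "anticodon"),
                            names(ann))) {
        refs[[col]] <- ifelse(is.na(m), refs[[col]], ann[[col]][m])
      }
      refs <- trna_references(refs$id, refs$sequence, refs$organism,
                              refs$compartment, refs$amino_acid, refs$anticodon)
    }
  }
  refs
}

#' Write tRNA references to FASTA
#'
#' @param refs A `dorq_references` collection.
#' @param path Output FASTA path (`.gz` for compressed output).
#' @return `path`, invisibly.
#' @export
write_trna_references <- function(refs, path) {
  hdr <- paste(refs$id, refs$organism, refs$compartment,
               refs$amino_acid, refs$anticodon, sep = "|")
  set <- Biostrings::DNAStringSet(refs$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, filepath = path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# ---- reads and FASTQ -------------------------------------------------------

#' Construct a read set
#'
#' @param id Read identifiers.
#' @param sequence DNA sequences.
#' @param quality Phred+33 quality strings, same lengths as `sequence`.
#' @return A `dorq_reads` data frame.
#' @export
dorq_reads <- function(id, sequence, quality) {
  if (any(nchar(sequence) != nchar(quality))) {
    dorq_error("sequence and quality lengths differ", "dorq_length_mismatch_error")
  }
  out <- data.frame(id = as.character(id), sequence = as.character(sequence),
                    quality = as.character(quality), stringsAsFactors = FALSE)
  class(out) <- c("dorq_reads", "data.frame")
  out
}

#' @export
print.dorq_reads <- function(x, ...) {
  cat(sprintf("read set: %d reads, lengths %d-%d nt\n", nrow(x),
              if (nrow(x)) min(nchar(x$sequence)) else 0L,
              if (nrow(x)) max(nchar(x$sequence)) else 0L))
  invisible(x)
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param quality Character vector of quality strings.
#' @return List of integer vectors.
#' @export
phred_decode <- function(quality) {
  lapply(quality, function(q) utf8ToInt(q) - 33L)
}

#' Encode integer Phred scores as a Phred+33 string
#'
#' @param scores Integer vector of per-base scores (0-93).
#' @return Single quality string.
#' @export
phred_encode <- function(scores) {
  if (any(scores < 0L | scores > 93L)) {
    dorq_error("Phred scores must lie in [0, 93] for +33 encoding", "dorq_phred_range_error")
  }
  intToUtf8(as.integer(scores) + 33L)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ path, gzip transparent.
#' @return A `dorq_reads` set.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropped metadata columns on plain FASTQ input
  set <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  dorq_reads(
    id = names(set),
    sequence = as.character(set),
    quality = as.character(Biostrings::quality(set))
  )
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads A `dorq_reads` set.
#' @param path Output path; `.gz` suffix enables gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  set <- Biostrings::DNAStringSet(reads$sequence)
  names(set) <- reads$id
  Biostrings::writeXStringSet(
    set, filepath = path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}
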