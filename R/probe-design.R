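#' Default Illumina-compatible adapter sequences
#'
#' P5 is prepended and P3 appended to the 40-nt recognition sequence, giving
#' the 87-nt full-length construct used for index PCR and sequencing.
#' @name adapters
#' @export
DEFAULT_P5 <- "AGACGTGTGCTCTTCCGATCT"

#' @rdname adapters
#' @export
DEFAULT_P3 <- "GATCGTCGGACTGTAGAACTCTGAAC"

#' Extract the 3'-terminal region of mature tRNA sequences
#'
#' The hybridization region targets the tRNA 3' end: few Watson-Crick-impeding
#' modifications sit there and 40 nt gives sufficient sequence discrimination
#' between families.
#'
#' @param sequence Character vector of mature sequences (5'->3').
#' @param length Region length in nt (default 40).
#' @return Character vector of 3' suffixes, orientation preserved.
#' @export
extract_3prime_region <- function(sequence, length = 40L) {
  n <- nchar(sequence)
  if (any(n < length)) {
    dorq_error(sprintf("sequence shorter than %d nt", length),
               "dorq_sequence_too_short_error")
  }
  substr(sequence, n - length + 1L, n)
}

#' Collapse 3' regions into probe families by edit distance
#'
#' Families are the connected components of the graph joining pairs of regions
#' at Levenshtein distance strictly below `threshold` (single-linkage
#' transitive closure — the unique order-independent equivalence grouping).
#' The family representative is the member sequence occurring most often among
#' the inputs; ties break lexicographically.
#'
#' @param regions Named character vector, id -> region sequence (equal lengths).
#' @param threshold Collapse threshold (default 6): pairs closer than this are
#'   merged into one species.
#' @return List of families, each `list(ids =, representative =)`, ordered by
#'   representative sequence.
#' @export
collapse_families <- function(regions, threshold = 6L) {
  if (is.null(names(regions)) || anyDuplicated(names(regions))) {
    dorq_error("regions must carry unique names", "dorq_duplicate_id_error")
  }
  if (threshold < 1L) dorq_error("threshold must be >= 1", "dorq_threshold_error")
  n <- length(regions)
  if (n == 1L) {
    return(list(list(ids = names(regions), representative = unname(regions))))
  }
  d <- levenshtein_matrix(unname(regions))
  adj <- d < threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  fams <- lapply(split(seq_len(n), memb), function(idx) {
    seqs <- unname(regions[idx])
    tab <- table(seqs)
    best <- names(tab)[tab == max(tab)]
    list(ids = sort(names(regions)[idx]), representative = min(best))
  })
  fams <- unname(fams)
  ord <- order(vapply(fams, `[[`, character(1L), "representative"),
               vapply(fams, function(f) f$ids[1L], character(1L)))
  fams[ord]
}

#' Build one quantification probe (cDOQ)
#'
#' The recognition sequence is the reverse complement of the family's 3'
#' region; the full construct is `p5 + recognition + p3` (87 nt with the
#' default adapters). The 5' dye follows the compartment: 6-FAM for cytosolic
#' families, Cy5 for mitochondrial.
#'
#' @param region Representative 3' region (tRNA orientation).
#' @param members Character vector of covered reference ids.
#' @param compartment Compartment of every member (`"cytosolic"` /
#'   `"mitochondrial"`); a mixed family is an error.
#' @param p5,p3 Adapter sequences.
#' @param name Probe family label.
#' @return One-row data frame with columns name, compartment, dye,
#'   recognition, construct, members, gc_fraction.
#' @export
build_probe <- function(region, members, compartment,
                        p5 = DEFAULT_P5, p3 = DEFAULT_P3, name = NULL) {
  compartment <- unique(compartment)
  if (length(compartment) != 1L || !compartment %in% VALID_COMPARTMENTS) {
    dorq_error("family spans cytosolic and mitochondrial references (or compartment unknown)",
               "dorq_mixed_compartment_error")
  }
  recognition <- reverse_complement(region)
  if (is.null(name)) name <- members[1L]
  data.frame(
    name = name,
    compartment = compartment,
    dye = if (compartment == "cytosolic") "6-FAM" else "Cy5",
    recognition = recognition,
    construct = paste0(p5, recognition, p3),
    members = paste(members, collapse = ","),
    gc_fraction = gc_fraction(recognition),
    stringsAsFactors = FALSE
  )
}

family_label <- function(refs, ids) {
  sub <- refs[match(ids, refs$id), , drop = FALSE]
  if (any(is.na(sub$amino_acid)) || any(is.na(sub$anticodon))) return(ids[1L])
  paste(sort(unique(paste0(sub$amino_acid, sub$anticodon))), collapse = "/")
}

#' Design a cDOQ probe set from a tRNA reference collection
#'
#' Extracts 3' 40-mers, collapses near-identical regions into families,
#' reverse-complements each representative and frames it with the P5/P3
#' adapters.
#'
#' @param refs A `dorq_references` collection with compartment annotation.
#' @param threshold Collapse threshold in edit distance (default 6).
#' @param p5,p3 Adapter sequences.
#' @param append_cca Append a 3'-CCA to references lacking one (genomic
#'   database entries often omit the post-transcriptional CCA; the
#'   hybridization region must match the mature molecule).
#' @param region_length Hybridization region length (default 40 nt).
#' @return A `dorq_probeset` object.
#' @export
design_probes <- function(refs, threshold = 6L, p5 = DEFAULT_P5, p3 = DEFAULT_P3,
                          append_cca = FALSE, region_length = 40L) {
  seqs <- refs$sequence
  if (append_cca) {
    seqs <- ifelse(endsWith(seqs, "CCA"), seqs, paste0(seqs, "CCA"))
  }
  regions <- setNames(extract_3prime_region(seqs, region_length), refs$id)
  fams <- collapse_families(regions, threshold)
  rows <- lapply(fams, function(f) {
    build_probe(
      region = f$representative,
      members = f$ids,
      compartment = unique(refs$compartment[match(f$ids, refs$id)]),
      p5 = p5, p3 = p3,
      name = family_label(refs, f$ids)
    )
  })
  probes <- do.call(rbind, rows)
  probes$name <- make.unique(probes$name, sep = "-")
  rownames(probes) <- NULL
  probe_set(probes, p5 = p5, p3 = p3, collapse_threshold = threshold)
}

#' Assemble a probe set object
#'
#' @param probes Data frame with columns name, compartment, dye, recognition,
#'   construct, members, gc_fraction.
#' @param p5,p3 Adapter sequences used for the constructs.
#' @param collapse_threshold Edit-distance threshold the set was designed at.
#' @return A `dorq_probeset`: list of `probes`, adapters, threshold, and the
#'   computed minimum pairwise recognition distance.
#' @export
probe_set <- function(probes, p5 = DEFAULT_P5, p3 = DEFAULT_P3,
                      collapse_threshold = 6L) {
  if (anyDuplicated(probes$name)) {
    dorq_error("probe names must be unique", "dorq_duplicate_id_error")
  }
  if (anyDuplicated(probes$recognition)) {
    dorq_error("recognition sequences must be unique", "dorq_duplicate_id_error")
  }
  min_d <- NA_integer_
  if (nrow(probes) >= 2L) {
    d <- levenshtein_matrix(probes$recognition)
    min_d <- min(d[upper.tri(d)])
  }
  structure(
    list(probes = probes, p5 = p5, p3 = p3,
         collapse_threshold = as.integer(collapse_threshold),
         min_pairwise_distance = min_d),
    class = "dorq_probeset"
  )
}

#' @export
print.dorq_probeset <- function(x, ...) {
  cat(sprintf("cDOQ probe set: %d probes (%d cytosolic/6-FAM, %d mitochondrial/Cy5)\n",
              nrow(x$probes),
              sum(x$probes$dye == "6-FAM"), sum(x$probes$dye == "Cy5")))
  cat(sprintf("construct length %d nt (P5 %d + recognition 40 + P3 %d)\n",
              nchar(x$probes$construct[1L]), nchar(x$p5), nchar(x$p3)))
  cat(sprintf("collapse threshold %d, min pairwise recognition distance %s\n",
              x$collapse_threshold,
              ifelse(is.na(x$min_pairwise_distance), "NA",
                     x$min_pairwise_distance)))
  invisible(x)
}

#' Validate probe-set specificity
#'
#' Reports the minimum pairwise Levenshtein distance between recognition
#' sequences (with the offending pair), all pairs below the collapse
#' threshold, per-probe GC fractions, and a pass/fail flag. Failure does not
#' abort design: the distance floor is a design criterion, not a hard
#' constraint.
#'
#' @param ps A `dorq_probeset` with at least 2 probes.
#' @return A `dorq_validation` list: `min_pairwise_distance`, `min_pair`,
#'   `below_threshold` (data frame), `gc` (data frame), `pass`.
#' @export
validate_probe_set <- function(ps) {
  probes <- ps$probes
  if (nrow(probes) < 2L) {
    dorq_error("validation needs at least 2 probes", "dorq_empty_input_error")
  }
  d <- levenshtein_matrix(probes$recognition)
  ut <- upper.tri(d)
  pairs <- which(ut, arr.ind = TRUE)
  dv <- d[ut]
  min_d <- min(dv)
  amin <- pairs[which.min(dv), ]
  below <- dv < ps$collapse_threshold
  report <- structure(
    list(
      min_pairwise_distance = as.integer(min_d),
      min_pair = c(probes$name[amin[1L]], probes$name[amin[2L]]),
      below_threshold = data.frame(
        probe_a = probes$name[pairs[below, 1L]],
        probe_b = probes$name[pairs[below, 2L]],
        distance = as.integer(dv[below]),
        stringsAsFactors = FALSE
      ),
      gc = data.frame(name = probes$name, gc_fraction = probes$gc_fraction,
                      stringsAsFactors = FALSE),
      collapse_threshold = ps$collapse_threshold,
      pass = !any(below)
    ),
    class = "dorq_validation"
  )
  report
}

#' @export
print.dorq_validation <- function(x, ...) {
  cat(sprintf("probe-set validation: %s\n", if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("minimum pairwise distance %d (%s vs %s); threshold %d\n",
              x$min_pairwise_distance, x$min_pair[1L], x$min_pair[2L],
              x$collapse_threshold))
  if (nrow(x$below_threshold)) {
    cat(sprintf("%d pair(s) below threshold:\n", nrow(x$below_threshold)))
    print.data.frame(x$below_threshold)
  }
  cat(sprintf("recognition GC fraction: %.2f-%.2f\n",
              min(x$gc$gc_fraction), max(x$gc$gc_fraction)))
  invisible(x)
}

# ---- probe-set I/O ---------------------------------------------------------

#' Write a probe set as TSV
#'
#' Column order is fixed: name, compartment, dye, recognition, construct,
#' members, gc_fraction.
#'
#' @param ps A `dorq_probeset`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_probe_tsv <- function(ps, path) {
  cols <- c("name", "compartment", "dye", "recognition", "construct",
            "members", "gc_fraction")
  write.table(ps$probes[, cols], file = path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a probe set from TSV
#'
#' Adapters are recovered from the construct/recognition columns; the
#' collapse threshold can be overridden if the set was designed at a
#' non-default value.
#'
#' @param path Probe TSV written by [write_probe_tsv()].
#' @param collapse_threshold Designed threshold (default 6).
#' @return A `dorq_probeset`.
#' @export
read_probe_tsv <- function(path, collapse_threshold = 6L) {
  probes <- read.delim(path, stringsAsFactors = FALSE,
                       colClasses = c(gc_fraction = "numeric"))
  pos <- regexpr(probes$recognition[1L], probes$construct[1L], fixed = TRUE)
  p5 <- substr(probes$construct[1L], 1L, pos - 1L)
  p3 <- substr(probes$construct[1L], pos + nchar(probes$recognition[1L]),
               nchar(probes$construct[1L]))
  probe_set(probes, p5 = p5, p3 = p3, collapse_threshold = collapse_threshold)
}

#' Export probe recognition sequences as FASTA
#'
#' This is the quantifier's reference set (one 40-mer per probe family).
#'
#' @param ps A `dorq_probeset`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_probe_fasta <- function(ps, path) {
  set <- Biostrings::DNAStringSet(ps$probes$recognition)
  names(set) <- ps$probes$name
  Biostrings::writeXStringSet(set, filepath = path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
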