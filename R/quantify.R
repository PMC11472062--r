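#' Trim reads to the recognition region
#'
#' Keeps the first `length` bases of each read (the cDOQ hybridization
#' sequence sits at the read start; the remainder is adapter). Reads shorter
#' than `length` are returned as `NA` and counted as a too-short outcome,
#' not an error.
#'
#' @param sequence Character vector of read sequences.
#' @param length Trim length (default 40).
#' @return Character vector; `NA` where the read is too short.
#' @export
trim_read <- function(sequence, length = 40L) {
  ifelse(nchar(sequence) < length, NA_character_,
         substr(sequence, 1L, length))
}

#' Assign trimmed reads to probes by bounded edit distance
#'
#' Exact hash lookup first; otherwise the unique probe within Levenshtein
#' distance `max_dist` of the read. Reads with no probe in radius, or with
#' two or more probes tied at the minimum distance, are unassigned (`NA`).
#' With a validated set at minimum pairwise distance `D`, any
#' `max_dist <= floor((D - 1) / 2)` guarantees by the triangle inequality
#' that at most one probe can sit within the radius; `strict = TRUE`
#' enforces that bound.
#'
#' @param trimmed Character vector of trimmed (40-nt) read sequences; `NA`
#'   entries pass through as `NA`.
#' @param probes A `dorq_probeset`.
#' @param max_dist Assignment radius (default 2, the largest radius with a
#'   uniqueness guarantee at the design floor distance of 6).
#' @param strict Enforce the uniqueness bound on `max_dist`.
#' @return Character vector of probe names, `NA` for unassigned.
#' @export
assign_read <- function(trimmed, probes, max_dist = 2L, strict = FALSE) {
  rec <- probes$probes$recognition
  nm <- probes$probes$name
  if (strict) {
    bound <- floor((probes$min_pairwise_distance - 1L) / 2L)
    if (is.na(bound) || max_dist > bound) {
      dorq_error(sprintf(
        "max_dist %d exceeds the uniqueness bound floor((%s-1)/2) = %s",
        max_dist, probes$min_pairwise_distance, bound), "dorq_radius_error")
    }
  }
  out <- nm[match(trimmed, rec)]
  todo <- which(is.na(out) & !is.na(trimmed))
  if (length(todo)) {
    uniq <- unique(trimmed[todo])
    d <- adist(uniq, rec)
    best <- apply(d, 1L, min)
    ties <- rowSums(d == best) > 1L
    hit <- best <= max_dist & !ties
    assigned <- rep(NA_character_, length(uniq))
    assigned[hit] <- nm[apply(d[hit, , drop = FALSE], 1L, which.min)]
    out[todo] <- assigned[match(trimmed[todo], uniq)]
  }
  out
}

#' Quantify a sample against a probe set
#'
#' Trims every read to the 40-nt recognition region, assigns it to a probe
#' within the edit-distance radius, and tabulates counts. The relative
#' abundances are counts over mapped reads (the paper's pipeline maps > 98%
#' of reads, so mapped- and total-read denominators nearly coincide);
#' reads-per-million uses the total-read denominator so both conventions are
#' available.
#'
#' @param reads A `dorq_reads` set or a FASTQ path.
#' @param probes A `dorq_probeset`.
#' @param max_dist Assignment radius (default 2).
#' @param strict Enforce the radius uniqueness bound (see [assign_read()]).
#' @param trim_length Recognition length (default 40).
#' @return A `dorq_abundance`: `table` (name, count, fraction, rpm),
#'   `totals` (total_reads, mapped_reads, too_short, unassigned),
#'   `mapping_rate`, `mean_q`.
#' @export
quantify_sample <- function(reads, probes, max_dist = 2L, strict = FALSE,
                            trim_length = 40L) {
  if (is.character(reads)) reads <- read_fastq(reads)
  if (nrow(reads) == 0L) {
    dorq_error("no reads to quantify", "dorq_empty_input_error")
  }
  trimmed <- trim_read(reads$sequence, trim_length)
  assigned <- assign_read(trimmed, probes, max_dist = max_dist, strict = strict)
  nm <- probes$probes$name
  counts <- table(factor(assigned, levels = nm))
  total <- nrow(reads)
  too_short <- sum(is.na(trimmed))
  mapped <- sum(!is.na(assigned))
  unassigned <- total - mapped - too_short
  tab <- data.frame(
    name = nm,
    count = as.integer(counts),
    fraction = if (mapped > 0L) as.numeric(counts) / mapped else NA_real_,
    rpm = 1e6 * as.numeric(counts) / total,
    stringsAsFactors = FALSE
  )
  qs <- unlist(phred_decode(reads$quality))
  structure(
    list(
      table = tab,
      totals = list(total_reads = total, mapped_reads = mapped,
                    too_short = too_short, unassigned = unassigned),
      mapping_rate = mapped / total,
      mean_q = mean(qs)
    ),
    class = "dorq_abundance"
  )
}

#' @export
print.dorq_abundance <- function(x, ...) {
  cat(sprintf("abundance table: %d probes, %d reads (%.1f%% mapped, %d too short, %d unassigned)\n",
              nrow(x$table), x$totals$total_reads, 100 * x$mapping_rate,
              x$totals$too_short, x$totals$unassigned))
  top <- x$table[order(-x$table$count), ]
  print.data.frame(utils::head(top, 8L), row.names = FALSE, digits = 4L)
  if (nrow(top) > 8L) cat(sprintf("... and %d more probes\n", nrow(top) - 8L))
  invisible(x)
}

#' Write an abundance table (CSV) and optional stats (JSON)
#'
#' @param ab A `dorq_abundance`.
#' @param path Output CSV path (columns name, count, fraction, rpm).
#' @param stats_path Optional JSON path for totals / mapping rate / mean Q.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(ab, path, stats_path = NULL) {
  write.csv(ab$table, path, row.names = FALSE, quote = FALSE)
  if (!is.null(stats_path)) {
    jsonlite::write_json(
      list(totals = ab$totals, mapping_rate = ab$mapping_rate,
           mean_q = ab$mean_q),
      stats_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Read an abundance table written by [write_abundance()]
#'
#' Totals are reconstructed from the counts; too-short and unassigned reads
#' are not recoverable from the CSV and are reported as zero.
#'
#' @param path Abundance CSV path.
#' @return A `dorq_abundance`.
#' @export
read_abundance <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  mapped <- sum(tab$count)
  total <- if (any(tab$rpm > 0)) {
    round(1e6 * tab$count[which.max(tab$rpm)] / max(tab$rpm))
  } else {
    mapped
  }
  structure(
    list(table = tab,
         totals = list(total_reads = total, mapped_reads = mapped,
                       too_short = 0L, unassigned = total - mapped),
         mapping_rate = mapped / total,
         mean_q = NA_real_),
    class = "dorq_abundance"
  )
}
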