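#' Generate a synthetic tRNA reference collection
#'
#' Produces `n_families` mature-length (default 76 nt) sequences ending in
#' CCA whose 3' 40-mers are mutually at Levenshtein distance >= `min_dist`
#' (rejection sampling), with round-robin cytosolic/mitochondrial
#' compartments. This is the fixture generator standing in for database
#' references, so the full pipeline runs without downloads.
#'
#' @param n_families Number of well-separated families (>= 1).
#' @param tail_length 3' region length that must be separated (default 40).
#' @param total_length Mature sequence length (default 76).
#' @param min_dist Minimum pairwise distance between 3' regions (default 6).
#' @param seed Optional RNG seed for reproducibility.
#' @param max_tries Rejection-sampling budget per family.
#' @return A `dorq_references` collection.
#' @export
generate_reference_set <- function(n_families, tail_length = 40L,
                                   total_length = 76L, min_dist = 6L,
                                   seed = NULL, max_tries = 1000L) {
  if (n_families < 1L) dorq_error("n_families must be >= 1", "dorq_generation_error")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  tails <- character(0L)
  for (i in seq_len(n_families)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- paste0(
        paste(sample(bases, tail_length - 3L, replace = TRUE), collapse = ""),
        "CCA"
      )
      if (length(tails) == 0L || min(adist(cand, tails)) >= min_dist) {
        tails <- c(tails, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      dorq_error("rejection sampling exhausted: could not place a new separated family",
                 "dorq_generation_error")
    }
  }
  body_len <- total_length - tail_length
  bodies <- vapply(seq_len(n_families), function(i) {
    paste(sample(bases, body_len, replace = TRUE), collapse = "")
  }, character(1L))
  anticodons <- vapply(seq_len(n_families), function(i) {
    paste(sample(bases, 3L, replace = TRUE), collapse = "")
  }, character(1L))
  aa_cycle <- rep_len(aa, n_families)
  trna_references(
    id = sprintf("tRNA-%s-%s-%d", aa_cycle, anticodons, seq_len(n_families)),
    sequence = paste0(bodies, tails),
    organism = "synthetic",
    compartment = rep_len(VALID_COMPARTMENTS, n_families),
    amino_acid = aa_cycle,
    anticodon = anticodons
  )
}

#' Per-family pool weights after index PCR
#'
#' Deterministic exponential amplification: after `cycles` cycles a family
#' with per-cycle efficiency `e` grows by `(1+e)^cycles`, so its pool weight
#' is `fraction * (1+e)^cycles`, renormalized. Equal efficiencies (or zero
#' cycles) leave the composition unchanged; differing efficiencies reproduce
#' the sequence-specific amplification bias seen at high cycle numbers.
#'
#' @param fractions Named non-negative fractions summing to 1.
#' @param efficiencies Named per-cycle efficiencies in `[0, 1]` covering all
#'   families in `fractions`.
#' @param cycles Non-negative integer number of PCR cycles.
#' @return Named fractions summing to 1.
#' @export
pcr_weights <- function(fractions, efficiencies, cycles) {
  if (cycles < 0L) dorq_error("cycles must be >= 0", "dorq_cycles_error")
  fam <- names(fractions)
  if (!all(fam %in% names(efficiencies))) {
    dorq_error("efficiencies must cover all families", "dorq_efficiency_error")
  }
  e <- efficiencies[fam]
  if (any(e < 0 | e > 1)) {
    dorq_error("efficiencies must lie in [0, 1]", "dorq_efficiency_error")
  }
  w <- fractions * (1 + e)^cycles
  w / sum(w)
}

check_composition <- function(composition, probe_names) {
  if (is.data.frame(composition)) {
    composition <- setNames(composition$fraction, composition$family)
  }
  if (is.null(names(composition))) {
    dorq_error("composition must be named by probe family", "dorq_composition_error")
  }
  if (!all(names(composition) %in% probe_names)) {
    dorq_error("composition contains families absent from the probe set",
               "dorq_composition_error")
  }
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9) {
    dorq_error("fractions must be non-negative and sum to 1 (tolerance 1e-9)",
               "dorq_composition_error")
  }
  composition
}

#' Simulate DORQ-seq reads from a pool composition
#'
#' Forward model of capture, index PCR and sequencing: each read's family is
#' drawn from the PCR-reweighted composition; the read is the probe's 40-nt
#' recognition sequence followed by P3 adapter bases up to `read_length`;
#' each base is substituted, independently with probability
#' `10^(-q_score/10)`, by a uniformly random different base. Per-read quality
#' strings dither between `floor(q)` and `floor(q)+1` so their mean equals
#' the configured `q_score` whenever `frac(q) * read_length` is an integer.
#'
#' @param probes A `dorq_probeset`.
#' @param composition Named fractions (or data frame `family,fraction`)
#'   summing to 1 over a subset of probe names.
#' @param n_reads Number of reads.
#' @param q_score Mean Phred quality (default 33.6, typical Illumina output).
#' @param pcr_cycles Index-PCR cycles (default 0: no amplification bias).
#' @param efficiencies Named per-family per-cycle efficiencies in `[0,1]`;
#'   default 1 for every family (unbiased amplification).
#' @param read_length Read length, between 40 and `40 + nchar(p3)`.
#' @param seed Optional RNG seed; identical seeds give byte-identical output.
#' @return A `dorq_reads` set with attributes `truth` (family per read) and
#'   `weights` (post-PCR sampling weights).
#' @export
simulate_reads <- function(probes, composition, n_reads, q_score = 33.6,
                           pcr_cycles = 0L, efficiencies = NULL,
                           read_length = 50L, seed = NULL) {
  composition <- check_composition(composition, probes$probes$name)
  max_len <- 40L + nchar(probes$p3)
  if (read_length < 40L || read_length > max_len) {
    dorq_error(sprintf("read_length must lie in [40, %d]", max_len),
               "dorq_read_length_error")
  }
  if (n_reads < 1L) dorq_error("n_reads must be >= 1", "dorq_empty_input_error")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(efficiencies)) {
    efficiencies <- setNames(rep(1, length(composition)), names(composition))
  }
  w <- if (pcr_cycles > 0L) {
    pcr_weights(composition, efficiencies, pcr_cycles)
  } else {
    composition
  }
  fam <- sample(names(w), n_reads, replace = TRUE, prob = w)
  rec <- setNames(probes$probes$recognition, probes$probes$name)
  templates <- setNames(
    substr(paste0(rec[names(w)], probes$p3), 1L, read_length),
    names(w)
  )
  seqs <- unname(templates[fam])

  p <- 10^(-q_score / 10)
  n_err <- rbinom(n_reads, read_length, p)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(read_length, n_err[i])
    for (j in pos) {
      cur <- substr(seqs[i], j, j)
      substr(seqs[i], j, j) <- sample(setdiff(bases, cur), 1L)
    }
  }

  qual <- quality_string(q_score, read_length)
  reads <- dorq_reads(
    id = sprintf("read_%07d", seq_len(n_reads)),
    sequence = seqs,
    quality = rep(qual, n_reads)
  )
  attr(reads, "truth") <- fam
  attr(reads, "weights") <- w
  reads
}

# dithered constant-mean quality string (see simulate_reads)
quality_string <- function(q_score, read_length) {
  lo <- floor(q_score)
  k <- round((q_score - lo) * read_length)
  phred_encode(c(rep(lo + 1, k), rep(lo, read_length - k)))
}

#' Analytic sequencing-error statistics at a given quality
#'
#' Closed-form Phred arithmetic: the per-base error probability is
#' `10^(-q/10)`, its reciprocal the expected base calls per error, and
#' `1 - (1-p)^L` the fraction of L-nt reads carrying at least one error.
#'
#' @param q_score Mean Phred quality (> 0).
#' @param read_length Read length in bases (default 40, the recognition
#'   region).
#' @return List with `per_base_error`, `base_calls_per_error`,
#'   `frac_reads_with_error`.
#' @examples
#' expected_error_stats(33.6, 40)
#' @export
expected_error_stats <- function(q_score, read_length = 40L) {
  if (q_score <= 0) dorq_error("q_score must be > 0", "dorq_quality_error")
  p <- 10^(-q_score / 10)
  list(
    per_base_error = p,
    base_calls_per_error = 1 / p,
    frac_reads_with_error = 1 - (1 - p)^read_length
  )
}

#' Simulate a spike-in standard-addition series
#'
#' Known masses of the anchor family's in-vitro transcript are added to the
#' sample mass vector before normalization (the IVT is indistinguishable from
#' the native family at the recognition level), each level is sequenced and
#' quantified, and the anchor's signal is collected per spike level.
#'
#' @param probes A `dorq_probeset`.
#' @param base_fractions Named endogenous fractions summing to 1.
#' @param anchor Anchor family name (must appear in `base_fractions`).
#' @param spike_ng Spike masses in ng (default `c(0, 1, 2)`).
#' @param total_ng Total endogenous input mass in ng (default 25).
#' @param n_reads Reads per level (default 1e5).
#' @param q_score Mean Phred quality (default 33.6).
#' @param seed Optional seed covering the whole series.
#' @param ... Further arguments passed to [simulate_reads()].
#' @return A `dorq_calibration_series`: list with `series` (data frame
#'   `spike_ng, signal, count, total_reads`; signal is the anchor's
#'   reads-per-million), `total_input_ng`, `anchor_family`,
#'   `endogenous_ng` (programmed truth), and the per-level abundance tables.
#' @export
simulate_spike_series <- function(probes, base_fractions, anchor,
                                  spike_ng = c(0, 1, 2), total_ng = 25,
                                  n_reads = 1e5, q_score = 33.6,
                                  seed = NULL, ...) {
  base_fractions <- check_composition(base_fractions, probes$probes$name)
  if (!anchor %in% names(base_fractions)) {
    dorq_error("anchor family absent from base composition", "dorq_anchor_missing_error")
  }
  if (!is.null(seed)) set.seed(seed)
  mass <- base_fractions * total_ng
  tables <- vector("list", length(spike_ng))
  rows <- vector("list", length(spike_ng))
  for (i in seq_along(spike_ng)) {
    m <- mass
    m[anchor] <- m[anchor] + spike_ng[i]
    comp <- m / sum(m)
    reads <- simulate_reads(probes, comp, n_reads = n_reads,
                            q_score = q_score, seed = NULL, ...)
    tab <- quantify_sample(reads, probes)
    tables[[i]] <- tab
    row <- tab$table[tab$table$name == anchor, ]
    rows[[i]] <- data.frame(spike_ng = spike_ng[i], signal = row$rpm,
                            count = row$count,
                            total_reads = tab$totals$total_reads)
  }
  structure(
    list(series = do.call(rbind, rows),
         total_input_ng = total_ng,
         anchor_family = anchor,
         endogenous_ng = unname(mass[anchor]),
         tables = tables),
    class = "dorq_calibration_series"
  )
}

#' @export
print.dorq_calibration_series <- function(x, ...) {
  cat(sprintf("standard-addition series: anchor %s in %.3g ng total input\n",
              x$anchor_family, x$total_input_ng))
  print.data.frame(x$series)
  invisible(x)
}
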