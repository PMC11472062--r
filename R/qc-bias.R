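#' Quality-score summary of a read set
#'
#' @param reads A `dorq_reads` set or FASTQ path.
#' @return List with `mean_q` (arithmetic mean Phred score over all bases),
#'   `per_position_mean` (NA-padded to the longest read), and
#'   `frac_bases_below_q30`.
#' @export
qscore_summary <- function(reads) {
  if (is.character(reads)) reads <- read_fastq(reads)
  if (nrow(reads) == 0L) dorq_error("no reads", "dorq_empty_input_error")
  qs <- phred_decode(reads$quality)
  maxlen <- max(lengths(qs))
  mat <- vapply(qs, function(v) c(v, rep(NA_real_, maxlen - length(v))),
                numeric(maxlen))
  mat <- matrix(mat, nrow = maxlen)
  all_q <- unlist(qs)
  list(
    mean_q = mean(all_q),
    per_position_mean = rowMeans(mat, na.rm = TRUE),
    frac_bases_below_q30 = mean(all_q < 30)
  )
}

#' PCR-cycle bias profile across abundance tables
#'
#' Per-family fold change of the mapped fraction at each cycle relative to
#' the baseline (lowest) cycle. Families with zero baseline fraction are
#' flagged (`NA` fold change), not divided. Fold changes beyond the log2
#' threshold are flagged as biased.
#'
#' @param tables Named list of `dorq_abundance`, names = cycle numbers.
#' @param baseline Baseline cycle; default the smallest cycle present.
#' @param log2_threshold Flag threshold on `|log2 fold change|` (default 0.5).
#' @return A `dorq_bias_profile` data frame (cycle, family, fold_change,
#'   log2_fc, flagged) with attributes `baseline_cycle`, `max_enrichment`,
#'   `max_depletion`.
#' @export
pcr_bias_profile <- function(tables, baseline = NULL, log2_threshold = 0.5) {
  cycles <- as.numeric(names(tables))
  if (length(tables) < 2L || any(is.na(cycles))) {
    dorq_error("need >= 2 tables named by cycle number", "dorq_baseline_missing_error")
  }
  if (is.null(baseline)) baseline <- min(cycles)
  if (!baseline %in% cycles) {
    dorq_error(sprintf("baseline cycle %s not among the tables", baseline),
               "dorq_baseline_missing_error")
  }
  base_tab <- tables[[which(cycles == baseline)[1L]]]$table
  base_frac <- setNames(base_tab$fraction, base_tab$name)
  rows <- lapply(which(cycles != baseline), function(i) {
    tab <- tables[[i]]$table
    fr <- setNames(tab$fraction, tab$name)
    fam <- names(base_frac)
    fc <- ifelse(base_frac > 0, fr[fam] / base_frac, NA_real_)
    data.frame(
      cycle = cycles[i], family = fam, fold_change = unname(fc),
      log2_fc = unname(log2(fc)),
      flagged = unname(is.na(fc) | abs(log2(fc)) > log2_threshold),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  structure(
    out,
    baseline_cycle = baseline,
    max_enrichment = max(out$fold_change, na.rm = TRUE),
    max_depletion = min(out$fold_change, na.rm = TRUE),
    class = c("dorq_bias_profile", "data.frame")
  )
}

#' @export
print.dorq_bias_profile <- function(x, ...) {
  cat(sprintf("PCR-cycle bias profile (baseline cycle %s)\n",
              attr(x, "baseline_cycle")))
  cat(sprintf("max enrichment %.3f, max depletion %.3f, %d family-cycle pairs flagged\n",
              attr(x, "max_enrichment"), attr(x, "max_depletion"),
              sum(x$flagged, na.rm = TRUE)))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4L)
  if (nrow(x) > 10L) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Correlation of amplification bias with recognition GC content
#'
#' Pearson correlation between per-family `log2` fold change and the GC
#' fraction of the recognition sequence — the check that observed bias is
#' (or is not) explained by base composition.
#'
#' @param profile A `dorq_bias_profile`.
#' @param probes The `dorq_probeset` the tables were quantified against.
#' @param cycle Which cycle of the profile to use; default the largest.
#' @return List `pearson_r`, `r_squared`, `n`, `flag` (non-NA when the
#'   correlation is undefined and reported as 0).
#' @export
gc_bias_correlation <- function(profile, probes, cycle = NULL) {
  df <- as.data.frame(profile)
  if (is.null(cycle)) cycle <- max(df$cycle)
  df <- df[df$cycle == cycle & !is.na(df$log2_fc), ]
  gc <- setNames(probes$probes$gc_fraction, probes$probes$name)
  df$gc <- gc[df$family]
  df <- df[!is.na(df$gc), ]
  if (nrow(df) < 3L) {
    dorq_error("need >= 3 families with defined fold change and GC",
               "dorq_degenerate_error")
  }
  if (var(df$gc) == 0) {
    dorq_error("GC content has zero variance across families", "dorq_degenerate_error")
  }
  if (var(df$log2_fc) == 0) {
    return(list(pearson_r = 0, r_squared = 0, n = nrow(df),
                flag = "constant_fold_change"))
  }
  r <- stats::cor(df$log2_fc, df$gc)
  list(pearson_r = r, r_squared = r^2, n = nrow(df), flag = NA_character_)
}

#' Concordance of two abundance tables
#'
#' Simple linear regression of one pool's fractions on the other over shared
#' families. R-squared is the squared Pearson correlation (direction-free);
#' the adjusted value uses one predictor:
#' `adjR2 = 1 - (1 - R2) (n - 1) / (n - 2)`.
#'
#' @param a,b `dorq_abundance` tables sharing >= 3 family names.
#' @return List `r_squared`, `adjusted_r_squared`, `n`.
#' @export
compare_pools <- function(a, b) {
  shared <- intersect(a$table$name, b$table$name)
  if (length(shared) < 3L) {
    dorq_error("need >= 3 shared families", "dorq_insufficient_overlap_error")
  }
  x <- a$table$fraction[match(shared, a$table$name)]
  y <- b$table$fraction[match(shared, b$table$name)]
  r2 <- stats::cor(x, y)^2
  n <- length(shared)
  list(
    r_squared = r2,
    adjusted_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
    n = n
  )
}
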