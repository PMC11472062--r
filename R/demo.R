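#' Run the full synthetic end-to-end pipeline
#'
#' Generates a 38-family synthetic reference set, designs and validates the
#' probe set, simulates a pool with a 3-level spike-in series plus a
#' PCR-cycle pair, quantifies every library, fits the standard-addition
#' calibration and converts the whole pool to absolute masses. All artifacts
#' are written to `out_dir`; every random step flows from `seed`, so repeated
#' runs are byte-identical.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param n_families Number of synthetic families (default 38).
#' @param n_reads Reads per simulated library (default 1e5, the depth at
#'   which the calibration property is specified).
#' @param q_score Mean Phred quality (default 33.6).
#' @return Invisibly, a list with the probe set, validation report,
#'   calibration fit, absolute masses, bias profile and artifact paths.
#' @export
run_demo <- function(out_dir = tempfile("dorq_demo_"), seed = 1L,
                     n_families = 38L, n_reads = 1e5, q_score = 33.6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  refs <- generate_reference_set(n_families, seed = seed)
  write_trna_references(refs, file.path(out_dir, "references.fasta"))
  probes <- design_probes(refs)
  write_probe_tsv(probes, file.path(out_dir, "probes.tsv"))
  write_probe_fasta(probes, file.path(out_dir, "probes.fasta"))
  report <- validate_probe_set(probes)

  # pool composition: seeded Dirichlet-like draw, anchor near 3.7%
  nm <- probes$probes$name
  w <- rgamma(length(nm), shape = 2)
  base <- setNames(w / sum(w), nm)
  anchor <- nm[1L]
  base[anchor] <- 0.037
  base[-1L] <- base[-1L] * (1 - 0.037) / sum(base[-1L])

  series <- simulate_spike_series(probes, base, anchor,
                                  spike_ng = c(0, 1, 2), total_ng = 25,
                                  n_reads = n_reads, q_score = q_score)
  for (i in seq_along(series$tables)) {
    write_abundance(series$tables[[i]],
                    file.path(out_dir, sprintf("abundance_spike%d.csv", i - 1L)))
  }
  fit <- fit_standard_addition(series)
  jsonlite::write_json(
    list(slope = fit$slope, intercept = fit$intercept,
         r_squared = fit$r_squared, endogenous_ng = fit$endogenous_ng,
         anchor_family = fit$anchor_family),
    file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA
  )
  masses <- absolute_pool(series$tables[[1L]], anchor, fit$endogenous_ng)
  write.csv(masses, file.path(out_dir, "absolute_ng.csv"),
            row.names = FALSE, quote = FALSE)

  # cycle-bias pair: biased efficiencies, cycles 2 vs 9
  eff <- setNames(seq(0.5, 1, length.out = length(nm)), nm)
  tabs <- lapply(c(2L, 9L), function(cyc) {
    reads <- simulate_reads(probes, base, n_reads = n_reads,
                            q_score = q_score, pcr_cycles = cyc,
                            efficiencies = eff)
    quantify_sample(reads, probes)
  })
  names(tabs) <- c("2", "9")
  bias <- pcr_bias_profile(tabs)
  write.csv(as.data.frame(bias), file.path(out_dir, "bias_profile.csv"),
            row.names = FALSE, quote = FALSE)

  invisible(list(
    out_dir = out_dir, probes = probes, validation = report,
    fit = fit, absolute = masses, bias = bias
  ))
}
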