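make_table <- function(fractions, total = 1000L) {
  counts <- as.integer(round(fractions * total))
  structure(list(
    table = data.frame(name = names(fractions), count = counts,
                       fraction = as.numeric(fractions),
                       rpm = 1e6 * counts / total),
    totals = list(total_reads = total, mapped_reads = sum(counts),
                  too_short = 0L, unassigned = total - sum(counts)),
    mapping_rate = sum(counts) / total, mean_q = 33.6),
    class = "dorq_abundance")
}

test_that("quality summaries compute the arithmetic Phred mean", {
  r <- dorq_reads(c("a", "b"), c(strrep("A", 10), strrep("C", 10)),
                  c(phred_encode(rep(33, 10)), phred_encode(rep(33, 10))))
  expect_equal(qscore_summary(r)$mean_q, 33)
  r2 <- dorq_reads(c("a", "b"), c(strrep("A", 10), strrep("C", 10)),
                   c(phred_encode(rep(30, 10)), phred_encode(rep(40, 10))))
  s <- qscore_summary(r2)
  expect_equal(s$mean_q, 35)
  expect_equal(s$frac_bases_below_q30, 0)
  expect_equal(s$per_position_mean, rep(35, 10))
  expect_error(qscore_summary(dorq_reads(character(0), character(0),
                                         character(0))),
               class = "dorq_empty_input_error")
  # simulator emits the configured mean exactly (dithered encoding)
  ps <- make_test_probeset(2, seed = 281)
  reads <- simulate_reads(ps, setNames(c(0.5, 0.5), ps$probes$name), 100,
                          q_score = 33.6, read_length = 50, seed = 282)
  expect_equal(qscore_summary(reads)$mean_q, 33.6)
  # mean is invariant under read reordering
  set.seed(283)
  expect_equal(qscore_summary(reads[sample(nrow(reads)), ])$mean_q, 33.6)
})

test_that("cycle bias profiles equal the closed-form efficiency ratios", {
  fr <- c(A = 0.5, B = 0.5)
  eff <- c(A = 1.0, B = 0.5)
  tabs <- list("0" = make_table(fr),
               "6" = make_table(pcr_weights(fr, eff, 6)))
  prof <- pcr_bias_profile(tabs)
  expect_identical(attr(prof, "baseline_cycle"), 0)
  w6 <- pcr_weights(fr, eff, 6)
  expect_equal(setNames(prof$fold_change, prof$family), w6 / fr)
  expect_equal(round(unname(prof$fold_change), 3), c(1.698, 0.302))
  expect_equal(attr(prof, "max_enrichment"), max(w6 / fr))

  # identical tables: all fold changes one, nothing flagged
  same <- list("2" = make_table(fr), "6" = make_table(fr))
  p2 <- pcr_bias_profile(same)
  expect_true(all(p2$fold_change == 1))
  expect_false(any(p2$flagged))
  expect_equal(attr(p2, "max_enrichment"), 1)

  expect_error(pcr_bias_profile(tabs, baseline = 3),
               class = "dorq_baseline_missing_error")
  expect_error(pcr_bias_profile(tabs["0"]),
               class = "dorq_baseline_missing_error")
})

test_that("bias profiles over simulated cycle series match pcr_weights analytics", {
  ps <- make_test_probeset(6, seed = 291)
  nm <- ps$probes$name
  fr <- setNames(prop.table(rep(1, 6)), nm)
  eff <- setNames(seq(0.4, 1, length.out = 6), nm)
  tabs <- lapply(c(2, 9), function(cyc) {
    make_table(pcr_weights(fr, eff, cyc))
  })
  names(tabs) <- c("2", "9")
  prof <- pcr_bias_profile(tabs)
  want <- pcr_weights(fr, eff, 9) / pcr_weights(fr, eff, 2)
  expect_equal(setNames(prof$fold_change, prof$family), want)
})

test_that("GC-bias correlation detects constructed dependence and degeneracy", {
  ps <- make_test_probeset(8, seed = 301)
  nm <- ps$probes$name
  gc <- setNames(ps$probes$gc_fraction, nm)
  fr <- setNames(prop.table(rep(1, 8)), nm)
  # construct fold changes with log2 fc = 2 * GC -> perfect correlation
  fc <- 2^(2 * gc)
  tabs <- list("2" = make_table(fr), "6" = make_table(prop.table(fr * fc)))
  prof <- pcr_bias_profile(tabs)
  # renormalization shifts log2 fc by a constant; correlation is unaffected
  res <- gc_bias_correlation(prof, ps)
  expect_equal(res$pearson_r, 1)
  expect_equal(res$r_squared, 1)

  flat <- list("2" = make_table(fr), "6" = make_table(fr))
  res2 <- gc_bias_correlation(pcr_bias_profile(flat), ps)
  expect_equal(res2$pearson_r, 0)
  expect_identical(res2$flag, "constant_fold_change")

  const_gc <- ps
  const_gc$probes$gc_fraction <- 0.5
  expect_error(gc_bias_correlation(prof, const_gc),
               class = "dorq_degenerate_error")
})

test_that("independent fold changes and GC are mostly uncorrelated at n=38", {
  set.seed(311)
  rs <- replicate(100, {
    cor(rnorm(38), runif(38, 0.3, 0.7))
  })
  expect_lt(median(abs(rs)), 0.32)
  expect_gte(mean(abs(rs) < 0.32), 0.90)
})

test_that("pool comparison computes adjusted R-squared over shared families", {
  fr <- setNames(prop.table(1:8), letters[1:8])
  a <- make_table(fr)
  expect_equal(compare_pools(a, a),
               list(r_squared = 1, adjusted_r_squared = 1, n = 8))
  # fixed non-monotone permutation -> weak correlation
  perm <- fr[c(4, 7, 1, 8, 2, 5, 3, 6)]
  names(perm) <- letters[1:8]
  b <- make_table(perm)
  res <- compare_pools(a, b)
  expect_lt(res$r_squared, 0.5)
  expect_lt(res$adjusted_r_squared, res$r_squared)
  # symmetry of squared correlation
  set.seed(321)
  for (i in 1:5) {
    x <- make_table(setNames(prop.table(runif(8)), letters[1:8]))
    y <- make_table(setNames(prop.table(runif(8)), letters[1:8]))
    expect_equal(compare_pools(x, y)$r_squared, compare_pools(y, x)$r_squared)
  }
  small <- make_table(setNames(c(0.5, 0.5), c("a", "b")))
  expect_error(compare_pools(small, small),
               class = "dorq_insufficient_overlap_error")
})

test_that("replicate simulations of one composition are concordant", {
  ps <- make_test_probeset(10, seed = 331)
  comp <- setNames(prop.table(1:10), ps$probes$name)
  t1 <- quantify_sample(simulate_reads(ps, comp, 1e5, seed = 332), ps)
  t2 <- quantify_sample(simulate_reads(ps, comp, 1e5, seed = 333), ps)
  expect_gte(compare_pools(t1, t2)$r_squared, 0.99)
})
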