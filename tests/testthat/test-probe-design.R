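test_that("3' region extraction returns the terminal suffix", {
  s76 <- random_seq(76)
  expect_identical(extract_3prime_region(s76), substr(s76, 37, 76))
  s40 <- random_seq(40)
  expect_identical(extract_3prime_region(s40), s40)
  expect_error(extract_3prime_region(random_seq(39)),
               class = "dorq_sequence_too_short_error")
})

test_that("family collapsing follows connected components of the distance graph", {
  set.seed(51)
  # three well-separated 40-mers stay singletons
  far <- generate_reference_set(3, seed = 52)
  regions <- setNames(extract_3prime_region(far$sequence), far$id)
  expect_length(collapse_families(regions, 6), 3L)

  # duplicate 40-mers collapse
  a <- random_seq(40)
  dup <- c(x = a, y = a, z = regions[[1]])
  expect_length(collapse_families(dup, 6), 2L)

  # transitive chain: a-b dist 3, b-c dist 3, a-c dist 6 -> one family
  # (substituted positions are spread out so indel alignments cannot shortcut)
  b <- substitute_at(a, c(1, 8, 15))
  cc <- substitute_at(b, c(22, 29, 36))
  expect_identical(levenshtein(a, b), 3L)
  expect_identical(levenshtein(b, cc), 3L)
  expect_identical(levenshtein(a, cc), 6L)
  chain <- c(a = a, b = b, c = cc)
  fams <- collapse_families(chain, 6)
  expect_length(fams, 1L)
  expect_identical(fams[[1]]$ids, c("a", "b", "c"))
})

test_that("collapsing agrees with a brute-force component oracle on random inputs", {
  set.seed(61)
  for (rep in 1:10) {
    n <- 8
    base <- random_seq(12)
    seqs <- vapply(1:n, function(i) {
      substitute_at(base, sample(1:12, sample(0:6, 1)))
    }, character(1))
    names(seqs) <- paste0("s", 1:n)
    dmat <- levenshtein_matrix(seqs)
    for (thr in c(2, 4)) {
      want <- brute_components(dmat, thr)
      got <- collapse_families(seqs, thr)
      want_sets <- sort(vapply(split(names(seqs), want),
                               function(ids) paste(sort(ids), collapse = ","),
                               character(1)))
      expect_identical(partition_signature(got), unname(want_sets))
    }
  }
})

test_that("collapsing is order-independent and duplicates never add families", {
  set.seed(71)
  refs <- generate_reference_set(8, seed = 72)
  regions <- setNames(extract_3prime_region(refs$sequence), refs$id)
  base_sig <- partition_signature(collapse_families(regions, 6))
  for (i in 1:5) {
    perm <- sample(regions)
    expect_identical(partition_signature(collapse_families(perm, 6)), base_sig)
  }
  # adding an exact duplicate of an existing region keeps the family count
  withdup <- c(regions, dupe = unname(regions[[1]]))
  expect_length(collapse_families(withdup, 6),
                length(collapse_families(regions, 6)))
})

test_that("probe construction applies adapters, revcomp and the dye rule", {
  region <- random_seq(40)
  p <- build_probe(region, members = "m1", compartment = "cytosolic")
  expect_identical(nchar(p$construct), 87L)
  expect_identical(p$recognition, reverse_complement(region))
  expect_identical(p$construct, paste0(DEFAULT_P5, p$recognition, DEFAULT_P3))
  expect_identical(p$dye, "6-FAM")
  expect_identical(build_probe(region, "m1", "mitochondrial")$dye, "Cy5")
  expect_identical(build_probe(strrep("A", 40), "m1", "cytosolic")$recognition,
                   strrep("T", 40))
  expect_error(build_probe(region, c("m1", "m2"),
                           c("cytosolic", "mitochondrial")),
               class = "dorq_mixed_compartment_error")
  # arbitrary adapters: construct length = len(p5) + 40 + len(p3)
  set.seed(81)
  for (i in 1:5) {
    p5 <- random_seq(sample(5:30, 1)); p3 <- random_seq(sample(5:30, 1))
    pp <- build_probe(region, "m", "cytosolic", p5 = p5, p3 = p3)
    expect_identical(nchar(pp$construct), nchar(p5) + 40L + nchar(p3))
  }
})

test_that("validation reports min distance, below-threshold pairs and GC", {
  reg <- random_seq(40)
  dup <- probe_set(rbind(
    build_probe(reg, "a", "cytosolic", name = "A"),
    build_probe(substitute_at(reg, 1), "b", "cytosolic", name = "B"),
    build_probe(random_seq(40), "c", "cytosolic", name = "C")
  ))
  rep1 <- validate_probe_set(dup)
  expect_false(rep1$pass)
  expect_identical(rep1$min_pairwise_distance, 1L)
  expect_setequal(rep1$min_pair, c("A", "B"))
  expect_gte(nrow(rep1$below_threshold), 1L)

  set.seed(91)
  rand4 <- probe_set(do.call(rbind, lapply(1:4, function(i) {
    build_probe(random_seq(40), paste0("m", i), "cytosolic", name = paste0("P", i))
  })))
  rep2 <- validate_probe_set(rand4)
  d <- outer(rand4$probes$recognition, rand4$probes$recognition,
             Vectorize(function(x, y) as.integer(adist(x, y))))
  expect_identical(rep2$min_pairwise_distance, min(d[upper.tri(d)]))
  expect_true(rep2$pass)
  expect_equal(gc_fraction(strrep("ATGC", 10)), 0.5)
})

test_that("identical recognitions are rejected by the probe-set constructor", {
  reg <- random_seq(40)
  expect_error(probe_set(rbind(
    build_probe(reg, "a", "cytosolic", name = "A"),
    build_probe(reg, "b", "cytosolic", name = "B")
  )), class = "dorq_duplicate_id_error")
})

test_that("designed probe sets round-trip through TSV and FASTA", {
  ps <- make_test_probeset(6, seed = 103)
  tsv <- tempfile(fileext = ".tsv")
  write_probe_tsv(ps, tsv)
  header <- readLines(tsv, n = 1)
  expect_identical(header,
    "name\tcompartment\tdye\trecognition\tconstruct\tmembers\tgc_fraction")
  back <- read_probe_tsv(tsv)
  expect_identical(back$probes$recognition, ps$probes$recognition)
  expect_identical(back$p5, ps$p5)
  expect_identical(back$p3, ps$p3)
  expect_identical(back$min_pairwise_distance, ps$min_pairwise_distance)

  fa <- tempfile(fileext = ".fasta")
  write_probe_fasta(ps, fa)
  rec <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(rec), setNames(ps$probes$recognition,
                                               ps$probes$name))
  unlink(c(tsv, fa))
})

test_that("design on synthetic references yields separated, named families", {
  refs <- generate_reference_set(12, seed = 111)
  ps <- design_probes(refs)
  expect_identical(nrow(ps$probes), 12L)
  expect_gte(ps$min_pairwise_distance, 6L)
  expect_true(validate_probe_set(ps)$pass)
  expect_false(anyDuplicated(ps$probes$name) > 0)
  # append_cca completes immature references
  immature <- refs
  immature$sequence <- substr(refs$sequence, 1, 73)
  ps2 <- design_probes(immature, append_cca = TRUE)
  expect_true(all(endsWith(reverse_complement(ps2$probes$recognition), "CCA")))
})
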