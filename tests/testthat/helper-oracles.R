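# Independent oracles and fixture builders shared across the suite.

# Exponential-recursion Levenshtein oracle (only for short sequences).
lev_oracle <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  cost <- as.integer(substr(a, 1L, 1L) != substr(b, 1L, 1L))
  ta <- substr(a, 2L, nchar(a))
  tb <- substr(b, 2L, nchar(b))
  min(lev_oracle(ta, b) + 1L,
      lev_oracle(a, tb) + 1L,
      lev_oracle(ta, tb) + cost)
}

# Brute-force connected components on a precomputed distance matrix:
# repeated sweeps merging any pair below threshold until stable.
brute_components <- function(dmat, threshold) {
  n <- nrow(dmat)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && dmat[i, j] < threshold && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Apply substitutions at given 1-based positions, each to a fixed different base.
substitute_at <- function(seq, positions, to = NULL) {
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(positions)) {
    j <- positions[k]
    cur <- substr(seq, j, j)
    repl <- if (is.null(to)) setdiff(bases, cur)[1L] else to[k]
    substr(seq, j, j) <- repl
  }
  seq
}

# Small validated probe set from the synthetic generator.
make_test_probeset <- function(n = 5L, seed = 101L) {
  design_probes(generate_reference_set(n, seed = seed))
}

# Canonical form of a family partition (set of sorted id sets) for
# order-invariance comparisons.
partition_signature <- function(fams) {
  sets <- lapply(fams, function(f) paste(sort(f$ids), collapse = ","))
  sort(unlist(sets))
}
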