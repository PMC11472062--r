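---
title: "Hybridization-based tRNA pool quantification: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybridization-based tRNA pool quantification: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dorqseq)
```

## The measurement model

Hybridization-first tRNA quantification transfers the composition of a tRNA
pool onto a mixture of DNA oligos: each tRNA family hybridizes 1:1 with a
complementary quantification oligo (cDOQ), the duplexes are purified, and the
oligo mixture is amplified briefly and sequenced. Because the sequenced
molecules are unmodified DNA of known sequence, the analysis is counting, not
alignment inference: a read trimmed to its first 40 nt either is one of the
~40 recognition sequences (up to sequencing error) or it is noise.

`dorqseq` models and implements every computational stage of that pipeline.
This vignette records the models, the tunable parameters and the design
decisions that were genuinely open.

## Probe design

A probe is built from the 3'-terminal 40-mer of a mature tRNA reference. The
3' end is chosen because its modification landscape contains few
Watson–Crick-impeding marks and because 40 nt gives sufficient discrimination
between families while keeping oligos synthesizable. The recognition sequence
is the reverse complement of that 40-mer; the full construct is

```
5'-[dye]-P5 (21 nt) - recognition (40 nt) - P3 (26 nt)-3'   = 87 nt
```

with `P5 = AGACGTGTGCTCTTCCGATCT` and `P3 = GATCGTCGGACTGTAGAACTCTGAAC`, and
the dye 6-FAM for cytosolic families or Cy5 for mitochondrial ones (the two
channels can be imaged separately on a gel).

**Family collapsing.** References whose 40-mers are within Levenshtein
distance < 6 of one another cannot be told apart reliably and are collapsed
into one species. We take the connected components of the graph whose edges
join pairs below the threshold (single-linkage transitive closure). This is
the unique order-independent realization of "collapse similar sequences":
any permutation of the input yields the same partition, a property the test
suite asserts. The cost is that two members of one family can be farther
apart than the threshold (chaining); the validator therefore reports, rather
than enforces, cross-family distances.

**Representative choice.** Within a family the representative is the member
sequence that occurs most often among the input references, ties broken
lexicographically. Frequency weighting maximizes the fraction of reads that
match the probe exactly; any member would work for assignment because the
assignment radius (below) tolerates small deviations.

**CCA handling.** Mature tRNAs end in CCA, but genomic database entries often
lack it. References are assumed mature; `design_probes(append_cca = TRUE)`
appends CCA where absent so the recognition sequence matches the sequenced
molecule.

**Validation.** `validate_probe_set()` reports the minimum pairwise distance
with the offending pair, all pairs below the threshold, and per-probe GC.
A distance floor of 6 on 40 nt is 15% of the hybridizing sequence; empirical
work on oligo cross-hybridization recommends at least 10–12.5%, so 6 is a
comfortable floor. Validation failure is reported, not fatal: the floor is a
design criterion, and a user may knowingly keep a too-close pair.

## The forward simulator

The simulator is a first-class module: it defines the conditions under which
every downstream claim is tested.

* **References.** `generate_reference_set(n)` draws 76-nt sequences ending in
  CCA whose 3' 40-mers are mutually at distance ≥ 6 (rejection sampling with
  a retry budget), with round-robin cytosolic/mitochondrial annotation.
  76 nt is a canonical mature tRNA length; 37 random bases upstream of CCA
  make separation failures vanishingly rare, so rejection virtually never
  triggers at realistic family counts.
* **PCR bias.** Index PCR is modeled as deterministic exponential
  amplification: family *f* with per-cycle efficiency `e_f` in [0, 1] is
  reweighted by `(1+e_f)^c` after `c` cycles and renormalized. Equal
  efficiencies cancel exactly. A deterministic model (no stochastic
  duplication tree) is appropriate because the bias this emulates is
  reproducibly sequence-specific across replicates; its functional form
  between the measured cycle endpoints is a modeling stand-in, not a fitted
  mechanism. Capture (hybridization) efficiency defaults to 1 per family —
  the validated operating point of the assay — and can be folded into the
  composition if needed.
* **Reads.** A read is the recognition 40-mer followed by P3 adapter bases up
  to `read_length` (40–66 nt; default 50), mirroring the library layout in
  which trimming "to the first 40 nt" recovers the recognition sequence.
  Base-calling errors are independent per-base substitutions to a uniformly
  random different base with probability `p = 10^(-Q/10)`; indels are
  negligible on this platform class at these scales. Default `Q = 33.6`, a
  typical mean quality for a multiplexed run; at that quality `1/p ≈ 2291`
  base calls per error and `1-(1-p)^40 ≈ 1.7%` of 40-mers carry an error
  (`expected_error_stats()` gives the closed forms).
* **Qualities.** A mean quality like 33.6 is not representable as one
  Phred+33 character, so per-read quality strings dither between
  `floor(Q)` and `floor(Q)+1` with the count chosen so the per-read mean is
  exactly `Q` whenever `frac(Q)·L` is an integer (true at Q = 33.6 for
  L = 40 or 50). The error rate uses `Q` exactly, not the dithered values.
* **Determinism.** Every source of randomness flows from one seed; the same
  seed yields byte-identical FASTQ output.

What the simulator does **not** emulate: hybridization thermodynamics and
capture competition, gel purification losses, tRNA fragments, stochastic PCR
duplication, position-dependent quality decay, and indel errors. Passing
tests therefore demonstrate the correctness of the computational pipeline
under its stated error model, not the wet-lab behavior of a real library.

## Quantification

Reads are trimmed to their first 40 nt (shorter reads are a counted
`too_short` outcome). Assignment tries an exact hash lookup first — the vast
majority of reads at realistic quality — then finds the unique probe within
Levenshtein distance `max_dist`; ties at the minimum distance and
out-of-radius reads are `unassigned`. With a validated set at minimum
pairwise distance `D`, any radius `max_dist ≤ floor((D-1)/2)` guarantees by
the triangle inequality that at most one probe is reachable, so assignment
is provably unambiguous; the default `max_dist = 2` is the largest such
radius at the design floor `D = 6`. `strict = TRUE` enforces the bound. The
suite verifies specificity exhaustively: every ≤ 2-substitution mutant of
every recognition in a 5-probe set maps back to its origin.

Two denominators are reported because both are in use: `fraction` divides by
mapped reads (with > 98% of reads mapping the two conventions differ by
< 2%), `rpm` divides by total reads and scales by 10⁶. Counts conserve:
`mapped + too_short + unassigned = total` on every input.

## Standard-addition calibration

Known masses of an in-vitro transcript of one anchor family are added to the
sample before normalization; the IVT is indistinguishable from the native
family at the recognition level, which is precisely the standard-addition
premise. Ordinary least squares of signal (reads per million by default) on
spiked mass gives a line whose **y-intercept** is the zero-spike signal; when
the total input mass `M` is known, `ng = intercept / 1e6 · M` is the
endogenous mass of the anchor. The classical x-intercept estimate
(`-intercept/slope`) is computed alongside but the y-intercept conversion is
the default, matching how the assay is read out. R² is the squared Pearson
correlation of the series. RPM rather than raw counts is the default signal
so series with unequal sequencing depth remain comparable.

One subtlety: because spiking increases the total mass, the anchor's RPM is
`1e6·(m₀+s)/(M+s)` — slightly concave in the spike `s`, not exactly linear.
At the default conditions (anchor 3.7% of 25 ng, spikes 0–2 ng) the curvature
inflates the intercept-derived mass by ~1–2%, well inside the 5% recovery
tolerance the end-to-end property asserts; a practitioner spiking ≲ 10% of
the total input inherits the same small, conservative bias.

Negative intercepts (possible under extreme noise) are clamped to a zero
mass estimate and flagged rather than propagated as negative masses.

`absolute_pool()` extends the anchor's mass to every family by relative
abundance: `ng_f = anchor_ng · fraction_f / fraction_anchor`. Mass ratios
equal fraction ratios exactly and the anchor reproduces its input mass
exactly.

## QC and bias statistics

* `qscore_summary()` — arithmetic mean Phred score over all bases,
  per-position means, fraction of bases below Q30.
* `pcr_bias_profile()` — per-family fold change of the mapped fraction at
  each cycle relative to the baseline cycle (default: the smallest cycle in
  the series, the natural reference when amplification bias grows with cycle
  number). Families absent at baseline are flagged, not divided. Fold
  changes with `|log2| > 0.5` (default) are flagged as biased.
* `gc_bias_correlation()` — Pearson correlation of per-family log2 fold
  change with recognition GC fraction, the standard first suspect for
  amplification bias. A profile generated by the simulator's efficiency
  model reproduces the closed-form `(1+e)^Δc` ratios exactly, which the
  suite asserts.
* `compare_pools()` — squared Pearson correlation of two pools' fractions
  over shared families, with the one-predictor adjusted form
  `1 - (1-R²)(n-1)/(n-2)`.

Group-level significance testing across biological conditions is deliberately
out of scope: it is routine statistics downstream of the method core.

## Problem sizes and numerical choices

The test suite and the acceptance script use scaled problem sizes chosen as
the smallest that exercise each claim meaningfully: 10-family pools at 10⁵
reads per library for calibration properties (anchor counts ≈ 3,700 at the
3.7% operating point, giving ~1.6% multinomial noise on the anchor fraction),
2×10⁴ reads for mapping-rate checks, 200 repeated 10⁴-read simulations for
parameter-recovery envelopes, and a 38-family set — the size of a real
cytosolic probe panel — for design and demo runs. Edit-distance oracles run
exhaustively only at length ≤ 8 where exponential recursion is tractable.

Tie-breaks are deterministic everywhere (lexicographic representative,
first-minimum assignment with explicit tie detection); degenerate inputs
(zero signal variance, all-identical spike levels, empty FASTQ, missing
anchors, mixed-compartment families) raise typed conditions
(`dorq_*_error`) rather than producing NaNs.

## Known limitations

* Isodecoders within one family are not resolved — the method reports family
  aggregates by construction, and modification information is invisible to
  it.
* The efficiency model reproduces the phenomenology of cycle-dependent bias,
  not its mechanism; fitted efficiencies from real cycle series would be
  needed to predict a specific library's bias.
* Fractions use mapped reads as denominator; with mapping rates below ~90%
  the mapped/total distinction becomes material and both outputs should be
  inspected.
* The assignment radius guarantee assumes the probe set passed validation;
  on a degenerate set (min distance < 5) strict mode refuses radius 2, and
  non-strict assignment falls back to tie-flagging.
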