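Package: dorqseq
Title: Hybridization-Probe Design, Simulation and Absolute Quantification of tRNA Pools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for hybridization-based tRNA isoacceptor quantification by
    deep sequencing. Designs quantification oligos (cDOQs) from mature tRNA
    references by extracting 3'-terminal 40-mers and collapsing near-identical
    sequences with a Levenshtein-distance threshold, validates probe-set
    specificity, simulates the capture / index-PCR / sequencing process with a
    per-family amplification-efficiency bias model, classifies reads against
    the probe set with a bounded edit-distance radius, and converts relative
    abundances to absolute masses by spike-in standard-addition regression.
    Includes quality-score summaries, PCR-cycle bias profiling, GC-bias
    correlation and pool-to-pool concordance statistics, plus a synthetic
    reference and read generator so the full pipeline runs end-to-end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
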