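Package: moprof
Title: Positional Motif Enrichment Profiling for Scored DNA Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies where transcription factor binding motifs are
    enriched relative to an anchor point (transcription start site, peak
    summit, or a central motif) in a set of uniform-length scored DNA
    sequences. For each position weight matrix it scans both strands with a
    p-value calibrated log-odds threshold, builds a per-sequence match-score
    heatmap, and computes a positional enrichment profile: the partial
    Pearson correlation of smoothed motif match strength with the sequence
    score at every offset, controlling for sequence-wide GC content.
    Significance comes from a seeded permutation test with pointwise
    confidence bands and Benjamini-Yekutieli correction across all motifs
    and positions. Profiles are clustered with UPGMA on correlation
    distance, and results are rendered as per-motif figures, a sortable
    HTML results table with sparklines, and an HTML clustermap. A seeded
    synthetic fixture generator plants motifs at known offsets for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    patchwork,
    generics,
    parallel,
    tools,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
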