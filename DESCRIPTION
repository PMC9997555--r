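Package: mamut
Title: Mutation-Accumulation Line Mutation Rates and Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of mutation-accumulation (MA) experiments
    scored by whole-genome sequencing: line quality control (cross-
    contamination and depth filters), classification of called variants
    against a reference genome (region, synonymous/non-synonymous effect,
    four-fold degenerate sites, trinucleotide context, strand-collapsed
    substitution class, simple-sequence-repeat overlap for indels),
    mutation-rate estimation with exact Poisson (Garwood) confidence
    intervals, spectrum and context-rate tables, chi-square comparisons,
    and a per-gene mutation-enrichment scan. Includes a synthetic-data
    generator that emulates an MA experiment (toy genome with gene models
    and microsatellite tracts, Poisson mutation counts per line, a
    configurable six-class substitution spectrum with trinucleotide
    weighting, and indels with tunable repeat bias) so every stage can be
    exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
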