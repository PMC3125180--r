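Package: apmsnet
Title: Confidence-Scored Protein Interaction Networks from Replicated
    AP-MS Pull-Down Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Turns replicated affinity-purification mass-spectrometry
    (AP-MS) pull-down abundance tables (emPAI values over baits,
    biological replicates and elution fractions) plus a no-bait control
    into a confidence-scored bait-prey interaction network.  Implements
    the median-max summary statistic with control-median subtraction and
    bait normalization, a triplicate high-confidence filter with a
    sticky-bait equality rule, a bootstrap significance test that
    resamples replicate maxima against a pool of dissimilar-bait and
    control replicates, reciprocal-confirmation and functional-role
    agreement statistics with a permutation test, co-expression
    validation via centered Pearson correlation and Welch's t-test,
    reciprocal-best-hit ortholog mapping with interaction coverage,
    in-silico tryptic digestion and emPAI computation from peptide
    identifications, and a synthetic pull-down generator with planted
    complexes for end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
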