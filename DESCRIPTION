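Package: meltscore
Title: Thermal Proteome Profiling Analysis with Bootstrap Stability and
    Abundance Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for temperature-range thermal proteome
    profiling (TPP-TR) experiments quantified with 10-plex tandem mass tags.
    Reads and filters spectrum-level quantification tables by
    signal-to-interference and precursor-to-threshold quality measures,
    normalizes reporter intensities per temperature with a
    variance-stabilizing generalized-log transform, fits sigmoid melting
    curves and derives melting temperatures, computes bootstrap abundance
    and stability scores with empirical-null false discovery rates, calls
    hits, clusters fold-change profiles, summarizes protein-complex
    co-melting, and generates synthetic meltomes with known ground truth
    for benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
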